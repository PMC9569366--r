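#' @import methods
#' @importFrom stats median quantile sd cor rnorm runif rbinom rpois qnorm
#'   pnorm lm coef vcov predict as.formula model.matrix complete.cases AIC
#'   p.adjust var setNames pf pt anova resid rmultinom
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Configuration for the synthetic cohort generator
#'
#' Holds every knob of the cohort simulator: cohort and network geometry,
#' the block-covariance correlation levels, the planted standardized effect
#' sizes for the mediation/moderation structure, and the seed. Defaults
#' correspond to the study conditions the package emulates: a large
#' early-adolescent cohort observed at rest, with small (d ~ 0.2-0.4) belief
#' effects on network topology and cognition.
#'
#' @slot n_subjects number of subjects in the cohort.
#' @slot n_parcels number of parcels (atlas regions); layout counts must sum
#'   to this.
#' @slot n_timepoints samples per resting-state run.
#' @slot n_runs_per_subject runs per subject; the last run carries elevated
#'   noise so that run selection is non-trivial.
#' @slot network_layout data.frame with columns \code{network},
#'   \code{hemisphere}, \code{n_parcels} defining the parcellation.
#' @slot rho_within expected correlation of same-network parcel pairs.
#' @slot rho_between expected correlation of between-network pairs
#'   (strictly below \code{rho_within}).
#' @slot belief_topology_d target Cohen's d (belief level 5 vs level 1) on
#'   the targeted network property.
#' @slot target_network,target_hemisphere which network carries the planted
#'   topology effect.
#' @slot target_belief belief item carrying the planted effects.
#' @slot subject_sd between-subject SD of the within-network correlation
#'   propensity (the denominator scale for \code{belief_topology_d}).
#' @slot path_a_effect,path_b_effect,path_cprime_effect,moderation_effect
#'   standardized planted coefficients: belief -> mediator, mediator -> score,
#'   direct belief -> score, and belief x mediator interaction.
#' @slot noise_sd residual SD of the task-score model (standardized scale).
#' @slot n_sites number of acquisition sites.
#' @slot seed integer RNG seed; identical config + seed gives a bit-identical
#'   cohort.
#' @export
setClass("CohortConfig", representation(
  n_subjects = "integer", n_parcels = "integer", n_timepoints = "integer",
  n_runs_per_subject = "integer", network_layout = "data.frame",
  rho_within = "numeric", rho_between = "numeric",
  belief_topology_d = "numeric", target_network = "character",
  target_hemisphere = "character", target_belief = "character",
  subject_sd = "numeric",
  path_a_effect = "numeric", path_b_effect = "numeric",
  path_cprime_effect = "numeric", moderation_effect = "numeric",
  noise_sd = "numeric", n_sites = "integer", seed = "integer"
))

setValidity("CohortConfig", function(object) {
  bad <- function(field, why) sprintf("invalid CohortConfig field '%s': %s", field, why)
  if (object@n_subjects < 1L) return(bad("n_subjects", "must be >= 1"))
  if (object@n_parcels < 2L) return(bad("n_parcels", "must be >= 2"))
  if (object@n_timepoints < 4L) return(bad("n_timepoints", "must be >= 4"))
  if (object@n_runs_per_subject < 1L) return(bad("n_runs_per_subject", "must be >= 1"))
  nl <- object@network_layout
  if (!all(c("network", "hemisphere", "n_parcels") %in% names(nl)))
    return(bad("network_layout", "needs columns network, hemisphere, n_parcels"))
  if (sum(nl$n_parcels) != object@n_parcels)
    return(bad("network_layout", "parcel counts must sum to n_parcels"))
  if (object@rho_within < 0 || object@rho_within >= 1)
    return(bad("rho_within", "must lie in [0, 1)"))
  if (object@rho_between < 0 || object@rho_between > object@rho_within)
    return(bad("rho_between", "must lie in [0, rho_within]"))
  if (object@rho_between >= object@rho_within &&
      object@rho_within > 0)
    return(bad("rho_between", "must be strictly below rho_within"))
  eff <- c(object@belief_topology_d, object@path_a_effect, object@path_b_effect,
           object@path_cprime_effect, object@moderation_effect)
  if (any(!is.finite(eff))) return(bad("effects", "all planted effects must be finite"))
  if (!is.finite(object@noise_sd) || object@noise_sd <= 0)
    return(bad("noise_sd", "must be > 0"))
  if (object@subject_sd <= 0) return(bad("subject_sd", "must be > 0"))
  if (object@n_sites < 1L) return(bad("n_sites", "must be >= 1"))
  TRUE
})

#' One subject/run's parcel-by-time signal matrix
#'
#' @slot parcelIds ordered parcel identifiers (one per row of \code{data}).
#' @slot data numeric matrix, parcels x timepoints.
#' @slot motionFraction fraction of frames censored for motion, in [0, 1].
#' @export
setClass("ParcelTimeSeries", representation(
  parcelIds = "character", data = "matrix", motionFraction = "numeric"
))

setValidity("ParcelTimeSeries", function(object) {
  if (nrow(object@data) < 2L) return("a ParcelTimeSeries needs >= 2 parcels")
  if (length(object@parcelIds) != nrow(object@data))
    return("parcelIds length must equal nrow(data)")
  if (anyDuplicated(object@parcelIds)) return("parcelIds must be unique")
  if (anyNA(object@data)) return("time-series data must contain no missing values")
  if (object@motionFraction < 0 || object@motionFraction > 1)
    return("motionFraction must lie in [0, 1]")
  TRUE
})

#' Symmetric pairwise connectivity matrix
#'
#' @slot values symmetric parcels x parcels matrix with zero diagonal.
#' @slot method \code{"peak_crosscorr"} or \code{"mutual_information"}.
#' @slot peakLags symmetric integer matrix of peak lags (cross-correlation
#'   only), or NULL.
#' @export
setClass("ConnectivityMatrix", representation(
  values = "matrix", method = "character", peakLags = "matrixOrNULL"
))

setValidity("ConnectivityMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("connectivity values must be square")
  if (max(abs(v - t(v))) != 0) return("connectivity values must be exactly symmetric")
  if (any(diag(v) != 0)) return("connectivity diagonal must be exactly zero")
  if (!object@method %in% c("peak_crosscorr", "mutual_information"))
    return("method must be 'peak_crosscorr' or 'mutual_information'")
  if (object@method == "peak_crosscorr" && max(abs(v)) > 1 + 1e-12)
    return("peak cross-correlation values must satisfy |v| <= 1")
  TRUE
})

#' Thresholded weighted adjacency matrix
#'
#' Nonnegative weights survive only where the source connectivity met the
#' population threshold; all graph metrics consume this object.
#'
#' @slot weights symmetric nonnegative matrix, zero diagonal.
#' @slot thresholdUsed the threshold applied to the source connectivity.
#' @export
setClass("AdjacencyMatrix", representation(
  weights = "matrix", thresholdUsed = "numeric"
))

setValidity("AdjacencyMatrix", function(object) {
  w <- object@weights
  if (nrow(w) != ncol(w)) return("adjacency must be square")
  if (max(abs(w - t(w))) != 0) return("adjacency must be exactly symmetric")
  if (any(diag(w) != 0)) return("adjacency diagonal must be exactly zero")
  if (any(w < 0)) return("adjacency weights must be nonnegative")
  TRUE
})

#' Parcel-to-network assignment
#'
#' Maps every parcel to one (network, hemisphere) pair; defines the network
#' scale at which topological properties are summarized.
#'
#' @slot entries data.frame with columns \code{parcel_id}, \code{network},
#'   \code{hemisphere}.
#' @export
setClass("ParcellationMap", representation(entries = "data.frame"))

setValidity("ParcellationMap", function(object) {
  e <- object@entries
  if (!all(c("parcel_id", "network", "hemisphere") %in% names(e)))
    return("entries needs columns parcel_id, network, hemisphere")
  if (anyDuplicated(e$parcel_id)) return("each parcel must have exactly one entry")
  if (!all(e$hemisphere %in% c("left", "right", "midline")))
    return("hemisphere must be one of left, right, midline")
  if (length(unique(e$network)) < 1L) return("at least one network required")
  TRUE
})

## ---- accessors ----

#' Parcel identifiers of a time series or connectivity object
#' @param object a \code{ParcelTimeSeries} or \code{ConnectivityMatrix}
#' @return character vector of parcel ids
#' @export
setGeneric("parcelIds", function(object) standardGeneric("parcelIds"))
#' @rdname parcelIds
#' @export
setMethod("parcelIds", "ParcelTimeSeries", function(object) object@parcelIds)
#' @rdname parcelIds
#' @export
setMethod("parcelIds", "ConnectivityMatrix", function(object) rownames(object@values))

#' Signal matrix of a ParcelTimeSeries
#' @param object a \code{ParcelTimeSeries}
#' @return parcels x timepoints numeric matrix
#' @export
setGeneric("tsData", function(object) standardGeneric("tsData"))
#' @rdname tsData
#' @export
setMethod("tsData", "ParcelTimeSeries", function(object) object@data)

#' Motion-censored fraction of a run
#' @param object a \code{ParcelTimeSeries}
#' @export
setGeneric("motionFraction", function(object) standardGeneric("motionFraction"))
#' @rdname motionFraction
#' @export
setMethod("motionFraction", "ParcelTimeSeries", function(object) object@motionFraction)

#' Connectivity values
#' @param object a \code{ConnectivityMatrix}
#' @return the symmetric numeric matrix of pairwise association values
#' @export
setGeneric("connValues", function(object) standardGeneric("connValues"))
#' @rdname connValues
#' @export
setMethod("connValues", "ConnectivityMatrix", function(object) object@values)

#' Peak-lag matrix of a cross-correlation estimate
#' @param object a \code{ConnectivityMatrix}
#' @export
setGeneric("peakLags", function(object) standardGeneric("peakLags"))
#' @rdname peakLags
#' @export
setMethod("peakLags", "ConnectivityMatrix", function(object) object@peakLags)

#' Adjacency weights
#' @param object an \code{AdjacencyMatrix}
#' @export
setGeneric("adjWeights", function(object) standardGeneric("adjWeights"))
#' @rdname adjWeights
#' @export
setMethod("adjWeights", "AdjacencyMatrix", function(object) object@weights)

#' Threshold used to build an adjacency
#' @param object an \code{AdjacencyMatrix}
#' @export
setGeneric("thresholdUsed", function(object) standardGeneric("thresholdUsed"))
#' @rdname thresholdUsed
#' @export
setMethod("thresholdUsed", "AdjacencyMatrix", function(object) object@thresholdUsed)

#' Binary (0/1) view of an adjacency
#' @param object an \code{AdjacencyMatrix}
#' @return 0/1 matrix with 1 wherever the weight is strictly positive
#' @export
setGeneric("binarizedView", function(object) standardGeneric("binarizedView"))
#' @rdname binarizedView
#' @export
setMethod("binarizedView", "AdjacencyMatrix", function(object) {
  b <- (object@weights > 0) * 1
  dimnames(b) <- dimnames(object@weights)
  b
})

#' Entries of a ParcellationMap
#' @param object a \code{ParcellationMap}
#' @export
setGeneric("mapEntries", function(object) standardGeneric("mapEntries"))
#' @rdname mapEntries
#' @export
setMethod("mapEntries", "ParcellationMap", function(object) object@entries)

## ---- show ----

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf("CohortConfig: %d subjects, %d parcels x %d timepoints, %d run(s)\n",
              object@n_subjects, object@n_parcels, object@n_timepoints,
              object@n_runs_per_subject))
  cat(sprintf("  rho_within=%.3g rho_between=%.3g planted d=%.3g (%s %s / %s)\n",
              object@rho_within, object@rho_between, object@belief_topology_d,
              object@target_hemisphere, object@target_network, object@target_belief))
  cat(sprintf("  paths a=%.3g b=%.3g c'=%.3g mod=%.3g noise_sd=%.3g seed=%d\n",
              object@path_a_effect, object@path_b_effect, object@path_cprime_effect,
              object@moderation_effect, object@noise_sd, object@seed))
})

setMethod("show", "ParcelTimeSeries", function(object) {
  cat(sprintf("ParcelTimeSeries: %d parcels x %d timepoints (%.1f%% frames censored)\n",
              nrow(object@data), ncol(object@data), 100 * object@motionFraction))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  ut <- upperTriValues(object@values)
  cat(sprintf("ConnectivityMatrix (%s): %d parcels, median |upper tri| = %.3f\n",
              object@method, nrow(object@values), median(abs(ut))))
})

setMethod("show", "AdjacencyMatrix", function(object) {
  cat(sprintf("AdjacencyMatrix: %d nodes, %d edges (threshold %.4f)\n",
              nrow(object@weights), sum(object@weights[upper.tri(object@weights)] > 0),
              object@thresholdUsed))
})

setMethod("show", "ParcellationMap", function(object) {
  e <- object@entries
  cat(sprintf("ParcellationMap: %d parcels in %d (network, hemisphere) groups\n",
              nrow(e), nrow(unique(e[, c("network", "hemisphere")]))))
})

## ---- small shared helpers ----

#' Upper-triangle values of a square matrix
#' @param m square matrix
#' @return vector of strictly-upper-triangular values
#' @keywords internal
upperTriValues <- function(m) m[upper.tri(m)]

## Run code under a locally-seeded RNG, restoring the caller's RNG state.
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}
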