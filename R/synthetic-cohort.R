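## Synthetic cohort generator.
##
## Nothing here simulates scanner physics or hemodynamics: the generator
## plants exactly the statistical structure the downstream analysis assumes
## (covariate-dependent ordinal beliefs, belief-modulated block-correlated
## parcel signals, and task scores with direct, mediated and moderated
## belief effects), so every pipeline stage is testable without any
## restricted data.

## z-score that tolerates constant or length-one input
.zscore <- function(x) {
  s <- sd(x)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Belief items carried by the generator
#'
#' Seven religious-belief items and three religion-independent family-values
#' items, each answered on a 5-point ordinal scale (1 = not at all,
#' 5 = completely).
#'
#' @return named list with components \code{religious} and \code{nonreligious},
#'   character vectors of column names.
#' @export
beliefItems <- function() {
  list(
    religious = c("inner_strength", "god_first_family_second",
                  "teach_children_pray", "faith_if_all_taken",
                  "thank_god_daily", "follow_word_of_god",
                  "religion_important"),
    nonreligious = c("make_parents_happy", "good_represent_family",
                     "work_hard_family")
  )
}

#' Default network layout
#'
#' Eight canonical resting-state networks per hemisphere (salience/ventral
#' attention, dorsal attention, frontoparietal control, default mode,
#' temporoparietal, somatomotor, reward, other), with \code{n_parcels}
#' distributed as evenly as possible.
#'
#' @param n_parcels total number of parcels to distribute.
#' @return data.frame with columns \code{network}, \code{hemisphere},
#'   \code{n_parcels}.
#' @export
defaultNetworkLayout <- function(n_parcels = 100L) {
  networks <- c("salience_ventral_attention", "dorsal_attention",
                "frontoparietal_control", "default_mode", "temporoparietal",
                "somatomotor", "reward", "other")
  grid <- expand.grid(network = networks, hemisphere = c("left", "right"),
                      stringsAsFactors = FALSE)
  k <- nrow(grid)
  base <- n_parcels %/% k
  counts <- rep(base, k)
  extra <- n_parcels - base * k
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  if (any(counts < 2L))
    stop("n_parcels too small for the default 16-group layout (need >= 2 per group)")
  data.frame(network = grid$network, hemisphere = grid$hemisphere,
             n_parcels = as.integer(counts), stringsAsFactors = FALSE)
}

#' Construct a cohort-generator configuration
#'
#' Defaults describe the emulated study conditions: an early-adolescent
#' cohort with median age near 120 months, resting-state parcels organized
#' into canonical networks (within-network correlation 0.5, between-network
#' 0.08, resting runs of 375 frames), a small planted topology effect
#' (Cohen's d = 0.3,
#' level 5 vs level 1) on the right frontoparietal control network for the
#' "God is first, family is second" item, and small standardized mediation
#' paths (a = -0.15, b = 0.15, c' = -0.10) with a weak negative moderation.
#'
#' @param n_subjects,n_parcels,n_timepoints,n_runs_per_subject cohort and
#'   acquisition geometry.
#' @param network_layout data.frame of (network, hemisphere, n_parcels);
#'   counts must sum to \code{n_parcels}.
#' @param rho_within,rho_between block-covariance correlation levels.
#' @param belief_topology_d planted Cohen's d (level 5 vs 1) on the targeted
#'   network property.
#' @param target_network,target_hemisphere,target_belief where the planted
#'   effects live.
#' @param subject_sd between-subject SD of the within-network correlation
#'   propensity.
#' @param path_a_effect,path_b_effect,path_cprime_effect,moderation_effect
#'   standardized planted coefficients of the mediation/moderation diagram.
#' @param noise_sd residual SD of the task-score model on the standardized
#'   scale.
#' @param n_sites number of acquisition sites.
#' @param seed integer seed; same config + seed reproduces the cohort
#'   bit-identically.
#' @return a validated \code{\linkS4class{CohortConfig}}.
#' @export
cohortConfig <- function(n_subjects = 500L, n_parcels = 100L,
                         n_timepoints = 375L, n_runs_per_subject = 2L,
                         network_layout = defaultNetworkLayout(n_parcels),
                         rho_within = 0.5, rho_between = 0.08,
                         belief_topology_d = 0.3,
                         target_network = "frontoparietal_control",
                         target_hemisphere = "right",
                         target_belief = "god_first_family_second",
                         subject_sd = 0.06,
                         path_a_effect = -0.15, path_b_effect = 0.15,
                         path_cprime_effect = -0.10,
                         moderation_effect = -0.10,
                         noise_sd = 0.97, n_sites = 4L, seed = 1L) {
  asInt <- function(x, field) {
    if (length(x) != 1L || !is.finite(x) || x != round(x))
      stop(sprintf("invalid CohortConfig field '%s': must be a single integer", field))
    as.integer(x)
  }
  new("CohortConfig",
      n_subjects = asInt(n_subjects, "n_subjects"),
      n_parcels = asInt(n_parcels, "n_parcels"),
      n_timepoints = asInt(n_timepoints, "n_timepoints"),
      n_runs_per_subject = asInt(n_runs_per_subject, "n_runs_per_subject"),
      network_layout = network_layout,
      rho_within = rho_within, rho_between = rho_between,
      belief_topology_d = belief_topology_d,
      target_network = target_network,
      target_hemisphere = target_hemisphere,
      target_belief = target_belief,
      subject_sd = subject_sd,
      path_a_effect = path_a_effect, path_b_effect = path_b_effect,
      path_cprime_effect = path_cprime_effect,
      moderation_effect = moderation_effect,
      noise_sd = noise_sd, n_sites = asInt(n_sites, "n_sites"),
      seed = asInt(seed, "seed"))
}

#' Parcellation map implied by a configuration's network layout
#'
#' @param config a \code{\linkS4class{CohortConfig}}.
#' @return a \code{\linkS4class{ParcellationMap}} with parcels
#'   \code{P0001 ...} assigned in layout order.
#' @export
parcellationFromLayout <- function(config) {
  nl <- config@network_layout
  ids <- sprintf("P%04d", seq_len(config@n_parcels))
  entries <- data.frame(
    parcel_id = ids,
    network = rep(nl$network, nl$n_parcels),
    hemisphere = rep(nl$hemisphere, nl$n_parcels),
    stringsAsFactors = FALSE)
  new("ParcellationMap", entries = entries)
}

## Empirical income (Table-1-like) bracket probabilities, observed responses
## renormalized. Education runs 1 = did not finish high school .. 6 = advanced
## degree.
.incomeProbs <- c(145, 480, 738, 1496, 1653, 644) / 5156
.educationProbs <- c(300, 538, 914, 684, 1717, 1408) / 5561

#' Generate subject-level covariates
#'
#' Draws demographics with margins emulating a large early-adolescent cohort:
#' age centered at 120 months (IQR about 13), 52\% female, 67\% white, 20\%
#' Hispanic, six income and six education brackets cut from a correlated
#' latent bivariate normal (so income and education are positively
#' rank-correlated), BMI, family size, importance of family togetherness,
#' uniformly assigned site, and the motion-censored frame fraction of the
#' retained run (at most 10\%).
#'
#' @param config a \code{\linkS4class{CohortConfig}}.
#' @return data.frame, one row per subject; belief and score columns unset.
#' @export
generateCovariates <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  n <- config@n_subjects
  withLocalSeed(config@seed, {
    z <- matrix(rnorm(2L * n), ncol = 2L)
    z_edu <- z[, 1L]
    z_inc <- 0.45 * z[, 1L] + sqrt(1 - 0.45^2) * z[, 2L]
    cutFromProbs <- function(latent, probs) {
      cuts <- qnorm(cumsum(probs)[-length(probs)])
      findInterval(latent, cuts) + 1L
    }
    data.frame(
      subject_id = sprintf("S%05d", seq_len(n)),
      age_months = round(rnorm(n, mean = 120, sd = 13 / 1.349), 1),
      sex_female = rbinom(n, 1L, 0.521),
      race_white = rbinom(n, 1L, 0.671),
      ethnicity_hispanic = rbinom(n, 1L, 0.197),
      income_bracket = cutFromProbs(z_inc, .incomeProbs),
      education = cutFromProbs(z_edu, .educationProbs),
      bmi = round(pmax(12, rnorm(n, 18.8, 3.2)), 1),
      family_size = pmax(1L, 2L + rpois(n, 2.4)),
      togetherness = cutFromProbs(rnorm(n), c(0.02, 0.05, 0.18, 0.35, 0.40)),
      site = sprintf("site%02d", sample.int(config@n_sites, n, replace = TRUE)),
      motion_censored_fraction = round(runif(n, 0, 0.10), 4),
      stringsAsFactors = FALSE)
  })
}

#' Structural loadings of the ordinal-belief model
#'
#' @param income,education loadings of (z-scored) income bracket and
#'   education on the latent belief propensity; negative by default, so
#'   lower income/education goes with stronger beliefs.
#' @param religious_factor,nonreligious_factor loadings of the family-level
#'   religiosity and family-values factors on their respective items.
#' @param factor_cor correlation between the two family-level factors (makes
#'   religious and non-religious belief strengths positively correlated).
#' @export
beliefLoadings <- function(income = -0.25, education = -0.25,
                           religious_factor = 0.8, nonreligious_factor = 0.6,
                           factor_cor = 0.4) {
  list(income = income, education = education,
       religious_factor = religious_factor,
       nonreligious_factor = nonreligious_factor, factor_cor = factor_cor)
}

#' Fill in ordinal beliefs, attendance, and importance
#'
#' Each belief item is an ordinal cut of a latent normal: item latent =
#' income/education loadings on the z-scored brackets + a family-level factor
#' + item noise; cut points are the standard-normal quintiles, so with all
#' loadings zero the five levels are uniform. Youth service-attendance (0-4)
#' and importance-of-religion (1-4) load positively on the subject's mean
#' religious-belief strength.
#'
#' @param records covariate table from \code{\link{generateCovariates}}.
#' @param config a \code{\linkS4class{CohortConfig}}.
#' @param loadings see \code{\link{beliefLoadings}}.
#' @return \code{records} with the ten belief columns plus
#'   \code{attendance} and \code{importance} appended.
#' @export
generateBeliefs <- function(records, config, loadings = beliefLoadings()) {
  stopifnot(is.data.frame(records), is(config, "CohortConfig"))
  if (!all(c("income_bracket", "education") %in% names(records)))
    stop("records must carry covariates; run generateCovariates() first")
  n <- nrow(records)
  items <- beliefItems()
  zs <- .zscore
  withLocalSeed(config@seed + 1L, {
    z_inc <- zs(records$income_bracket)
    z_edu <- zs(records$education)
    f_rel <- rnorm(n)
    f_non <- loadings$factor_cor * f_rel +
      sqrt(max(0, 1 - loadings$factor_cor^2)) * rnorm(n)
    cuts <- qnorm(c(0.2, 0.4, 0.6, 0.8))
    drawItem <- function(factor_score, factor_loading) {
      latent <- loadings$income * z_inc + loadings$education * z_edu +
        factor_loading * factor_score + rnorm(n)
      findInterval(latent, cuts) + 1L
    }
    for (item in items$religious)
      records[[item]] <- drawItem(f_rel, loadings$religious_factor)
    for (item in items$nonreligious)
      records[[item]] <- drawItem(f_non, loadings$nonreligious_factor)
    mean_rel <- zs(rowMeans(as.matrix(records[items$religious])))
    att_latent <- 0.7 * mean_rel + rnorm(n)
    att_cuts <- qnorm(cumsum(c(0.27, 0.23, 0.15, 0.28))[1:4] /
                      sum(c(0.27, 0.23, 0.15, 0.28, 0.07)))
    records$attendance <- findInterval(att_latent, att_cuts)        # 0..4
    imp_latent <- 0.7 * mean_rel + rnorm(n)
    imp_cuts <- qnorm(cumsum(c(0.18, 0.16, 0.30))[1:3] /
                      sum(c(0.18, 0.16, 0.30, 0.36)))
    records$importance <- findInterval(imp_latent, imp_cuts) + 1L   # 1..4
  })
  records
}

## Per-subject within-network correlation targets: a global connectivity
## propensity (subject_sd scale) plus the planted belief-linked decrement on
## the target network. The decrement is sized so the level-5 vs level-1 gap
## equals belief_topology_d subject-level SDs.
.subjectRho <- function(record, u, config) {
  nl <- config@network_layout
  rho <- rep(config@rho_within + config@subject_sd * u, nrow(nl))
  tgt <- nl$network == config@target_network &
    nl$hemisphere == config@target_hemisphere
  belief <- record[[config@target_belief]]
  if (any(tgt) && !is.null(belief)) {
    dec <- config@belief_topology_d * config@subject_sd * (belief - 1) / 4
    rho[tgt] <- rho[tgt] - dec
  }
  pmin(pmax(rho, config@rho_between), 0.95)
}

#' Generate one subject's resting-state runs
#'
#' Signals are zero-mean Gaussian with a block covariance: unit variances,
#' correlation \code{rho_within} (minus the subject's belief-linked decrement
#' on the targeted network, plus subject-level propensity noise) within each
#' (network, hemisphere) block and \code{rho_between} elsewhere. The
#' covariance is checked for positive semi-definiteness before sampling.
#' Runs differ only in noise realization, except the last run, which
#' carries an artifact-like global additive signal that inflates all
#' pairwise correlations (the way residual motion does in real data), so
#' run selection by lowest median connectivity is exercised non-trivially
#' and correctly prefers a clean run.
#'
#' @param record one-row data.frame for the subject (covariates + beliefs).
#' @param config a \code{\linkS4class{CohortConfig}}.
#' @return list of \code{\linkS4class{ParcelTimeSeries}}, one per run.
#' @export
generateTimeSeries <- function(record, config) {
  stopifnot(is.data.frame(record), nrow(record) == 1L)
  idx <- as.integer(sub("^S", "", record$subject_id))
  ids <- sprintf("P%04d", seq_len(config@n_parcels))
  nl <- config@network_layout
  block <- rep(seq_len(nrow(nl)), nl$n_parcels)
  withLocalSeed(config@seed + 1000L + idx, {
    u <- rnorm(1L)
    rho_blocks <- .subjectRho(record, u, config)
    P <- config@n_parcels
    sigma <- matrix(config@rho_between, P, P)
    for (b in seq_len(nrow(nl))) {
      in_b <- block == b
      sigma[in_b, in_b] <- rho_blocks[b]
    }
    diag(sigma) <- 1
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch))
      stop("block covariance is not positive semi-definite; ",
           "use a smaller belief-related decrement (belief_topology_d * subject_sd)")
    Tn <- config@n_timepoints
    lapply(seq_len(config@n_runs_per_subject), function(r) {
      x <- t(matrix(rnorm(Tn * P), Tn, P) %*% ch)  # parcels x timepoints
      if (r == config@n_runs_per_subject && config@n_runs_per_subject > 1L) {
        ## artifact-corrupted run: a global additive signal inflates all
        ## pairwise correlations, raising this run's median connectivity
        artifact <- rnorm(Tn, sd = 0.8)
        x <- x + matrix(artifact, P, Tn, byrow = TRUE)
      }
      rownames(x) <- ids
      new("ParcelTimeSeries", parcelIds = ids, data = x,
          motionFraction = round(runif(1L, 0, 0.10), 4))
    })
  })
}

#' Emit subject-level mediator values directly ("matrix mode")
#'
#' The fast stats-only route: the mediator (a standardized network property)
#' is drawn as \code{a * z(belief) + sqrt(1 - a^2) * noise} with
#' \code{a = path_a_effect}, bypassing time-series generation. The
#' \code{"topology"} mode returns the subject's true within-network
#' correlation of the targeted network (the quantity the connectivity and
#' graph stages estimate), using the same per-subject seeds as
#' \code{\link{generateTimeSeries}}.
#'
#' @param records cohort table with beliefs filled.
#' @param config a \code{\linkS4class{CohortConfig}}.
#' @param mode \code{"matrix"} or \code{"topology"}.
#' @return numeric vector of mediator values, one per subject.
#' @export
simulateMediators <- function(records, config, mode = c("matrix", "topology")) {
  mode <- match.arg(mode)
  belief <- records[[config@target_belief]]
  if (is.null(belief)) stop("records lack the target belief column ",
                            config@target_belief)
  n <- nrow(records)
  if (mode == "matrix") {
    a <- config@path_a_effect
    zb <- .zscore(belief)
    withLocalSeed(config@seed + 2L,
                  a * zb + sqrt(max(0, 1 - a^2)) * rnorm(n))
  } else {
    nl <- config@network_layout
    tgt <- which(nl$network == config@target_network &
                 nl$hemisphere == config@target_hemisphere)[1L]
    if (is.na(tgt)) stop("target network not present in network_layout")
    vapply(seq_len(n), function(i) {
      idx <- as.integer(sub("^S", "", records$subject_id[i]))
      u <- withLocalSeed(config@seed + 1000L + idx, rnorm(1L))
      .subjectRho(records[i, , drop = FALSE], u, config)[tgt]
    }, numeric(1))
  }
}

#' Fill in task scores with planted direct, mediated and moderated effects
#'
#' Standardized-scale linear model: score* = c' z(belief) + b z(mediator) +
#' moderation z(belief) z(mediator) + small income/age/togetherness terms +
#' noise, rescaled so the Flanker-like task has median near 97 and IQR near
#' 19 (Card-Sort-like: 94/23; Matrix-Reasoning-like: 10/4, with only the
#' income term planted).
#'
#' @param records cohort table with beliefs filled.
#' @param mediator_values one mediator value per subject (see
#'   \code{\link{simulateMediators}}).
#' @param config a \code{\linkS4class{CohortConfig}}.
#' @return \code{records} with columns \code{flanker}, \code{card_sort},
#'   \code{matrix_reasoning} appended.
#' @export
generateTaskScores <- function(records, mediator_values, config) {
  n <- nrow(records)
  if (length(mediator_values) != n || anyNA(mediator_values)) {
    bad <- if (length(mediator_values) == n)
      records$subject_id[which(is.na(mediator_values))[1L]] else "(length mismatch)"
    stop("missing mediator value for subject ", bad)
  }
  zs <- .zscore
  zb <- zs(records[[config@target_belief]])
  zm <- zs(mediator_values)
  covar_betas <- c(income = 0.10, age = 0.05, together = -0.05)
  eta_sd <- sqrt(config@path_cprime_effect^2 + config@path_b_effect^2 +
                 config@moderation_effect^2 + sum(covar_betas^2) +
                 config@noise_sd^2)
  withLocalSeed(config@seed + 3L, {
    base <- config@path_cprime_effect * zb + config@path_b_effect * zm +
      config@moderation_effect * zb * zm +
      covar_betas["income"] * zs(records$income_bracket) +
      covar_betas["age"] * zs(records$age_months) +
      covar_betas["together"] * zs(records$togetherness)
    mk <- function(center, iqr) {
      eta <- base + config@noise_sd * rnorm(n)
      round(center + (iqr / 1.349) * eta / eta_sd, 2)
    }
    records$flanker <- mk(97, 19)
    records$card_sort <- mk(94, 23)
    mr_eta <- covar_betas["income"] * zs(records$income_bracket) + rnorm(n)
    records$matrix_reasoning <- round(10 + (4 / 1.349) * mr_eta /
                                        sqrt(1 + covar_betas["income"]^2), 2)
  })
  records
}

#' Generate a complete synthetic cohort
#'
#' Runs the four generator stages in order. In \code{"matrix"} mode the
#' mediator is emitted directly and no time series are produced; in
#' \code{"topology"} mode each subject also receives simulated resting-state
#' runs and the mediator used for the scores is the subject's true targeted
#' within-network correlation.
#'
#' @param config a \code{\linkS4class{CohortConfig}}.
#' @param mode \code{"matrix"} (fast, stats-only) or \code{"topology"}
#'   (full time-series route).
#' @param loadings belief-model loadings, see \code{\link{beliefLoadings}}.
#' @return list with elements \code{cohort} (data.frame including a
#'   \code{mediator} column), \code{map}
#'   (\code{\linkS4class{ParcellationMap}}), and \code{timeseries} (list of
#'   per-subject run lists, or NULL in matrix mode).
#' @export
simulateCohort <- function(config, mode = c("matrix", "topology"),
                           loadings = beliefLoadings()) {
  mode <- match.arg(mode)
  rec <- generateCovariates(config)
  rec <- generateBeliefs(rec, config, loadings)
  ts_list <- NULL
  if (mode == "topology") {
    ts_list <- lapply(seq_len(nrow(rec)), function(i)
      generateTimeSeries(rec[i, , drop = FALSE], config))
    names(ts_list) <- rec$subject_id
  }
  med <- simulateMediators(rec, config, mode)
  rec <- generateTaskScores(rec, med, config)
  rec$mediator <- med
  list(cohort = rec, map = parcellationFromLayout(config), timeseries = ts_list)
}
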