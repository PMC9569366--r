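## Connectivity estimation: peak cross-correlation and mutual information,
## run selection, and the population-based threshold that keeps only
## moderate-to-high correlation values in the adjacency matrices.

.checkVariance <- function(ts) {
  v <- apply(tsData(ts), 1L, sd)
  if (any(v == 0))
    stop("zero-variance signal for parcel ", parcelIds(ts)[which(v == 0)[1L]])
}

#' Peak cross-correlation connectivity
#'
#' For each parcel pair the Pearson correlation of the overlapping,
#' per-lag re-centered and re-normalized segments is computed at every lag
#' in \code{[-max_lag, max_lag]}; the stored value is the signed correlation
#' at the lag maximizing \code{|rho|}. Ties go to the smallest \code{|lag|},
#' negative before positive. With \code{max_lag = 0} this is the ordinary
#' Pearson correlation matrix.
#'
#' @param ts a \code{\linkS4class{ParcelTimeSeries}}.
#' @param max_lag nonnegative integer lag window (samples); must be below
#'   half the run length.
#' @return a \code{\linkS4class{ConnectivityMatrix}} with
#'   \code{method = "peak_crosscorr"} and the peak-lag matrix filled.
#' @export
peakCrossCorr <- function(ts, max_lag = 5L) {
  stopifnot(is(ts, "ParcelTimeSeries"))
  max_lag <- as.integer(max_lag)
  Tn <- ncol(tsData(ts))
  if (max_lag < 0L) stop("max_lag must be nonnegative")
  if (max_lag >= Tn / 2) stop("max_lag must be below half the number of timepoints")
  .checkVariance(ts)
  x <- t(tsData(ts))                      # timepoints x parcels
  P <- ncol(x)
  ## cross-correlation matrices for lags 0..max_lag; C_tau[i, j] =
  ## cor(x_i[1:(T-tau)], x_j[(1+tau):T]); negative lags are the transpose
  cc <- lapply(0:max_lag, function(tau) {
    if (tau == 0L) cor(x)
    else suppressWarnings(cor(x[seq_len(Tn - tau), , drop = FALSE],
                              x[(tau + 1L):Tn, , drop = FALSE]))
  })
  v <- cc[[1L]]
  lags <- matrix(0L, P, P)
  ## lag priority order after lag 0: -1, +1, -2, +2, ...; a later candidate
  ## replaces the incumbent only on a strictly larger |rho|
  if (max_lag > 0L) {
    best <- abs(v)
    for (tau in 1:max_lag) {
      for (s in c(-1L, 1L)) {
        cand <- if (s < 0L) t(cc[[tau + 1L]]) else cc[[tau + 1L]]
        take <- abs(cand) > best
        take[is.na(take)] <- FALSE
        v[take] <- cand[take]
        lags[take] <- s * tau
        best[take] <- abs(cand[take])
      }
    }
  }
  ## enforce exact symmetry: for pair (i, j) the candidate set over signed
  ## lags is symmetric, but ties across strictly-equal |rho| at +/-tau are
  ## resolved identically for both orientations by the loop above only when
  ## values match exactly; mirror the upper triangle to guarantee it
  v[lower.tri(v)] <- t(v)[lower.tri(v)]
  lags[lower.tri(lags)] <- -t(lags)[lower.tri(lags)]
  diag(v) <- 0
  diag(lags) <- 0L
  dimnames(v) <- dimnames(lags) <- list(parcelIds(ts), parcelIds(ts))
  v <- pmin(pmax(v, -1), 1)
  new("ConnectivityMatrix", values = v, method = "peak_crosscorr",
      peakLags = lags)
}

#' Plug-in mutual information connectivity
#'
#' Mutual information (in nats) from the joint equal-width two-dimensional
#' histogram of each signal pair, with \code{n_bins} bins per axis spanning
#' each signal's own range. The diagonal is forced to zero.
#'
#' @param ts a \code{\linkS4class{ParcelTimeSeries}}.
#' @param n_bins number of histogram bins per axis (>= 2).
#' @return a \code{\linkS4class{ConnectivityMatrix}} with
#'   \code{method = "mutual_information"}.
#' @export
mutualInformation <- function(ts, n_bins = 16L) {
  stopifnot(is(ts, "ParcelTimeSeries"))
  if (n_bins < 2L) stop("n_bins must be >= 2")
  .checkVariance(ts)
  x <- tsData(ts)
  P <- nrow(x)
  Tn <- ncol(x)
  ## precompute per-parcel bin assignments (equal-width over own range)
  bins <- t(vapply(seq_len(P), function(i) {
    r <- range(x[i, ])
    b <- floor((x[i, ] - r[1L]) / (r[2L] - r[1L]) * n_bins) + 1L
    as.integer(pmin(b, n_bins))
  }, integer(Tn)))
  v <- matrix(0, P, P)
  for (i in seq_len(P - 1L)) {
    for (j in (i + 1L):P) {
      joint <- tabulate((bins[i, ] - 1L) * n_bins + bins[j, ],
                        nbins = n_bins * n_bins) / Tn
      jm <- matrix(joint, n_bins, n_bins, byrow = TRUE)  # rows: i, cols: j
      pi_ <- rowSums(jm)
      pj_ <- colSums(jm)
      nz <- jm > 0
      v[i, j] <- v[j, i] <-
        sum(jm[nz] * log(jm[nz] / (outer(pi_, pj_)[nz])))
    }
  }
  dimnames(v) <- list(parcelIds(ts), parcelIds(ts))
  new("ConnectivityMatrix", values = v, method = "mutual_information",
      peakLags = NULL)
}

#' Marginal histogram entropy of one parcel's signal
#'
#' Entropy (nats) of the equal-width histogram; equals the mutual
#' information of a signal with itself under the same binning.
#'
#' @param x numeric signal vector.
#' @param n_bins bins per axis.
#' @export
histogramEntropy <- function(x, n_bins = 16L) {
  r <- range(x)
  if (r[1L] == r[2L]) stop("constant signal has no histogram entropy")
  b <- pmin(floor((x - r[1L]) / (r[2L] - r[1L]) * n_bins) + 1L, n_bins)
  p <- tabulate(b, nbins = n_bins) / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Select the analysis run: lowest overall median connectivity
#'
#' Brain regions at rest are weakly synchronized, so the run with the lowest
#' median of upper-triangle connectivity values is retained. Ties go to the
#' earliest run.
#'
#' @param runs list of \code{\linkS4class{ConnectivityMatrix}} objects.
#' @return integer index into \code{runs}.
#' @export
selectRun <- function(runs) {
  if (length(runs) == 0L) stop("no runs supplied")
  med <- vapply(runs, function(r) median(upperTriValues(connValues(r))),
                numeric(1))
  which.min(med)  # which.min returns the first minimum: lowest index on ties
}

#' Population-based connectivity threshold
#'
#' Per subject, the moderate-outlier cutoff q = median + 1.5 IQR of the
#' upper-triangle connectivity values is computed; the returned threshold is
#' the upper bound of the normal-theory 95\% confidence interval of the mean
#' of q across subjects, mean(q) + 1.96 sd(q) / sqrt(n). Only values at or
#' above this threshold enter the adjacency matrices.
#'
#' @param matrices list of per-subject
#'   \code{\linkS4class{ConnectivityMatrix}} objects (>= 2 subjects).
#' @param method \code{"normal"} (default) or \code{"bootstrap"} (percentile
#'   bootstrap of the mean of q, seeded).
#' @param n_boot,seed bootstrap controls (bootstrap method only).
#' @return single numeric threshold.
#' @export
populationThreshold <- function(matrices, method = c("normal", "bootstrap"),
                                n_boot = 2000L, seed = 1L) {
  method <- match.arg(method)
  if (length(matrices) < 2L)
    stop("population threshold needs >= 2 subjects; for a single subject ",
         "pass a per-subject threshold to applyThreshold() directly")
  q <- vapply(matrices, function(m) {
    ut <- upperTriValues(connValues(m))
    median(ut) + 1.5 * (quantile(ut, 0.75, names = FALSE) -
                        quantile(ut, 0.25, names = FALSE))
  }, numeric(1))
  n <- length(q)
  if (method == "normal") {
    s <- sd(q)
    if (is.na(s)) s <- 0
    mean(q) + 1.96 * s / sqrt(n)
  } else {
    withLocalSeed(seed, {
      boots <- vapply(seq_len(n_boot), function(b)
        mean(q[sample.int(n, n, replace = TRUE)]), numeric(1))
      quantile(boots, 0.975, names = FALSE)
    })
  }
}

#' Threshold a connectivity matrix into a weighted adjacency
#'
#' Values at or above the threshold are kept as edge weights; everything
#' below — including all negative correlations — is zeroed. With
#' \code{on_abs = TRUE} the comparison uses \code{|v|} and the absolute
#' value is stored.
#'
#' @param matrix a \code{\linkS4class{ConnectivityMatrix}}.
#' @param thr finite numeric threshold.
#' @param on_abs threshold on the magnitude instead of the signed value.
#' @return an \code{\linkS4class{AdjacencyMatrix}}.
#' @export
applyThreshold <- function(matrix, thr, on_abs = FALSE) {
  stopifnot(is(matrix, "ConnectivityMatrix"), is.finite(thr))
  v <- connValues(matrix)
  w <- if (on_abs) abs(v) * (abs(v) >= thr) else v * (v >= thr)
  w[w < 0] <- 0
  diag(w) <- 0
  dimnames(w) <- dimnames(v)
  new("AdjacencyMatrix", weights = w, thresholdUsed = thr)
}
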