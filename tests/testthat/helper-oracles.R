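# Independent brute-force oracles for graph metrics, and small fixture
# builders. These deliberately use different algorithms from the package
# (Floyd-Warshall path enumeration, exhaustive partition search, matrix
# exponential series, characteristic-polynomial roots).

makeAdj <- function(w, thr = 0) {
  if (is.null(rownames(w))) {
    ids <- sprintf("P%04d", seq_len(nrow(w)))
    dimnames(w) <- list(ids, ids)
  }
  new("AdjacencyMatrix", weights = w, thresholdUsed = thr)
}

makeConn <- function(v, method = "peak_crosscorr") {
  if (is.null(rownames(v))) {
    ids <- sprintf("P%04d", seq_len(nrow(v)))
    dimnames(v) <- list(ids, ids)
  }
  new("ConnectivityMatrix", values = v, method = method, peakLags = NULL)
}

makeTS <- function(m, motion = 0.05) {
  ids <- sprintf("P%04d", seq_len(nrow(m)))
  rownames(m) <- ids
  new("ParcelTimeSeries", parcelIds = ids, data = m, motionFraction = motion)
}

symRand <- function(n, p = 0.5, weighted = TRUE) {
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  edges <- runif(sum(ut)) < p
  vals <- if (weighted) runif(sum(ut), 0.2, 1) else 1
  w[ut] <- edges * vals
  w <- w + t(w)
  w
}

# mean inverse shortest-path distance (Floyd-Warshall on 1/weight lengths)
oracleEfficiency <- function(w, binary = FALSE) {
  n <- nrow(w)
  if (n < 2) return(NA_real_)
  len <- matrix(Inf, n, n)
  pos <- w > 0
  len[pos] <- if (binary) 1 else 1 / w[pos]
  diag(len) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (len[i, k] + len[k, j] < len[i, j])
          len[i, j] <- len[i, k] + len[k, j]
  inv <- 1 / len
  diag(inv) <- 0
  inv[is.infinite(len)] <- 0
  sum(inv) / (n * (n - 1))
}

# all set partitions of n labelled items as restricted growth strings
setPartitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxblock) {
    k <- length(prefix)
    if (k == n) { out[[length(out) + 1]] <<- prefix; return(invisible()) }
    for (b in seq_len(maxblock + 1))
      rec(c(prefix, b), max(maxblock, b))
  }
  rec(integer(0), 0L)
  out
}

oracleQ <- function(w, membership) {
  two_m <- sum(w)
  if (two_m == 0) return(NA_real_)
  k <- rowSums(w)
  q <- 0
  for (c in unique(membership)) {
    inc <- membership == c
    q <- q + sum(w[inc, inc]) / two_m - (sum(k[inc]) / two_m)^2
  }
  q
}

# exhaustive maximum-modularity partition
oracleModularity <- function(w) {
  parts <- setPartitions(nrow(w))
  qs <- vapply(parts, function(p) oracleQ(w, p), numeric(1))
  best <- which.max(qs)
  list(membership = parts[[best]], Q = qs[best])
}

# ln(trace(expm(A))/n) by direct series summation
oracleNaturalConnectivity <- function(w, terms = 80L) {
  n <- nrow(w)
  S <- diag(n)
  term <- diag(n)
  for (k in seq_len(terms)) {
    term <- term %*% w / k
    S <- S + term
  }
  log(sum(diag(S)) / n)
}

# largest eigenvalue via Faddeev-LeVerrier characteristic polynomial + polyroot
oracleMaxEigen <- function(w) {
  n <- nrow(w)
  a <- numeric(n)
  M <- w
  a[1] <- -sum(diag(M))
  if (n > 1) {
    for (k in 2:n) {
      M <- w %*% (M + a[k - 1] * diag(n))
      a[k] <- -sum(diag(M)) / k
    }
  }
  roots <- polyroot(c(rev(a), 1))
  max(Re(roots))
}

oracleTransitivity <- function(w) {
  b <- (w > 0) * 1
  n <- nrow(b)
  tri <- 0; triples <- 0
  for (i in seq_len(n))
    for (j in seq_len(n))
      for (k in seq_len(n)) {
        if (i == j || j == k || i == k) next
        if (b[i, j] && b[j, k]) {
          triples <- triples + 1
          if (b[i, k]) tri <- tri + 1
        }
      }
  if (triples == 0) NA_real_ else tri / triples
}

adjustedRandIndex <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / choose2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
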