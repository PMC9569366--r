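# analytic graphs used throughout
K3 <- function() makeAdj(matrix(1, 3, 3) - diag(3))
path3 <- function() {
  w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- w[2, 3] <- w[3, 2] <- 1
  makeAdj(w)
}
star5 <- function() {
  w <- matrix(0, 5, 5); w[1, 2:5] <- w[2:5, 1] <- 1
  makeAdj(w)
}

test_that("global efficiency matches analytic and enumerated values", {
  expect_equal(globalEfficiency(K3()), 1.0)
  expect_equal(globalEfficiency(path3()), 5 / 6)
  expect_equal(globalEfficiency(makeAdj(matrix(0, 4, 4))), 0)
  expect_true(is.na(globalEfficiency(makeAdj(matrix(0, 1, 1)))))
})

test_that("clustering coefficients match triangle counting", {
  expect_equal(globalClustering(K3()), 1.0)
  expect_equal(unname(localClustering(K3())), rep(1, 3))
  expect_equal(globalClustering(path3()), 0.0)
  ## triangle plus pendant edge: 3 triangles / 5 connected triples
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 3] <- w[1, 3] <- w[3, 4] <- 1
  w <- pmax(w, t(w))
  expect_equal(globalClustering(makeAdj(w)), 0.6)
  ## no connected triples -> undefined
  single_edge <- matrix(0, 3, 3); single_edge[1, 2] <- single_edge[2, 1] <- 1
  expect_true(is.na(globalClustering(makeAdj(single_edge))))
})

test_that("modularity maximization recovers planted communities", {
  ## two disjoint triangles: exhaustive-search optimum is the two blocks, Q = 0.5
  w <- matrix(0, 6, 6)
  w[1:3, 1:3] <- 1; w[4:6, 4:6] <- 1; diag(w) <- 0
  adj <- makeAdj(w)
  res <- modularityQ(adj)
  oracle <- oracleModularity(w)
  expect_equal(res$Q, 0.5, tolerance = 1e-12)
  expect_equal(oracle$Q, 0.5, tolerance = 1e-12)
  expect_equal(adjustedRandIndex(res$membership, oracle$membership), 1)

  ## complete graph: the single community has Q = 0
  k4 <- matrix(1, 4, 4) - diag(4)
  expect_equal(modularityQ(makeAdj(k4))$Q, 0, tolerance = 1e-12)

  ## planted two-block weighted graph
  set.seed(20)
  blocks <- rep(1:2, each = 5)
  wb <- matrix(0.05, 10, 10)
  wb[blocks == 1, blocks == 1] <- 0.9
  wb[blocks == 2, blocks == 2] <- 0.9
  diag(wb) <- 0
  resb <- modularityQ(makeAdj(wb))
  expect_equal(adjustedRandIndex(resb$membership, blocks), 1)

  edgeless <- modularityQ(makeAdj(matrix(0, 4, 4)))
  expect_true(is.na(edgeless$Q))
})

test_that("small-worldness separates random and small-world regimes", {
  set.seed(30)
  er <- igraph::as_adjacency_matrix(
    igraph::sample_gnp(40, 0.25), sparse = FALSE)
  sig_er <- smallWorldness(makeAdj(er * 1), n_nulls = 10, seed = 5)
  expect_lt(abs(as.numeric(sig_er) - 1), 0.2)

  ws <- igraph::as_adjacency_matrix(
    igraph::sample_smallworld(1, 40, 4, 0.1), sparse = FALSE)
  ws <- pmin(ws, 1)
  sig_ws <- smallWorldness(makeAdj(ws * 1), n_nulls = 10, seed = 5)
  expect_gt(as.numeric(sig_ws), 1)

  ## determinism under seed
  expect_identical(as.numeric(smallWorldness(makeAdj(ws * 1), 5, seed = 9)),
                   as.numeric(smallWorldness(makeAdj(ws * 1), 5, seed = 9)))

  ## triangle-free guard: null clustering 0 -> undefined
  expect_true(is.na(smallWorldness(star5(), n_nulls = 3, seed = 1)))

  ## disconnected input flagged and computed on the largest component
  w <- matrix(0, 8, 8)
  w[1:5, 1:5] <- er[1:5, 1:5]
  s <- smallWorldness(makeAdj(w), n_nulls = 3, seed = 2)
  expect_true(attr(s, "largest_component_used"))
})

test_that("spectral metrics match analytic eigenvalues and independent oracles", {
  expect_equal(spectralStability(K3()), 2.0, tolerance = 1e-12)
  expect_equal(spectralStability(makeAdj(matrix(0, 4, 4))), 0)
  expect_equal(spectralStability(star5()), 2.0, tolerance = 1e-12)

  expect_equal(naturalConnectivity(makeAdj(matrix(0, 5, 5))), 0)
  expect_equal(naturalConnectivity(K3()),
               log((exp(2) + 2 * exp(-1)) / 3), tolerance = 1e-12)

  set.seed(40)
  for (k in 1:5) {
    w <- symRand(8, p = 0.5)
    adj <- makeAdj(w)
    expect_equal(naturalConnectivity(adj), oracleNaturalConnectivity(w),
                 tolerance = 1e-10)
    expect_equal(spectralStability(adj), oracleMaxEigen(w), tolerance = 1e-8)
  }
})

test_that("eigenvector centrality and degree match analytic cases", {
  k4 <- makeAdj(matrix(1, 4, 4) - diag(4))
  expect_equal(unname(eigenvectorCentrality(k4)), rep(1, 4), tolerance = 1e-8)

  cen <- eigenvectorCentrality(star5())
  expect_equal(unname(cen[1]), 1.0, tolerance = 1e-8)
  expect_equal(unname(cen[2:5]), rep(0.5, 4), tolerance = 1e-8)

  expect_equal(unname(nodeDegree(path3())), c(1L, 2L, 1L))
  edgeless <- makeAdj(matrix(0, 3, 3))
  expect_true(all(is.na(eigenvectorCentrality(edgeless))))
  expect_equal(unname(nodeDegree(edgeless)), c(0L, 0L, 0L))

  ## agrees with a dense eigendecomposition oracle on weighted graphs
  set.seed(41)
  w <- symRand(7, p = 0.7)
  v_pkg <- eigenvectorCentrality(makeAdj(w))
  ev <- eigen(w, symmetric = TRUE)$vectors[, 1]
  ev <- abs(ev) / max(abs(ev))
  expect_equal(unname(v_pkg), ev, tolerance = 1e-6)
})

test_that("median connectivity respects scope and matches a sort-based oracle", {
  v <- matrix(0, 4, 4)
  v[1, 2] <- 0.4; v[1, 3] <- 0.1; v[1, 4] <- 0.2
  v[2, 3] <- 0.3; v[2, 4] <- 0.25; v[3, 4] <- 0.15
  v <- v + t(v)
  conn <- makeConn(v)
  map <- new("ParcellationMap", entries = data.frame(
    parcel_id = sprintf("P%04d", 1:4),
    network = c("a", "a", "b", "b"),
    hemisphere = "left", stringsAsFactors = FALSE))
  mc <- medianConnectivity(conn, map, "a", "left")
  expect_equal(mc$within, 0.4)
  expect_equal(mc$outside, median(c(0.1, 0.2, 0.3, 0.25)))

  expect_equal(median(c(0.1, 0.2, 0.3)), 0.2)  # odd-count median convention

  set.seed(50)
  vr <- symRand(9, p = 1); diag(vr) <- 0
  connr <- makeConn(vr / (max(vr) + 1e-9))
  mapr <- new("ParcellationMap", entries = data.frame(
    parcel_id = sprintf("P%04d", 1:9),
    network = rep(c("a", "b", "c"), each = 3),
    hemisphere = "left", stringsAsFactors = FALSE))
  mcr <- medianConnectivity(connr, mapr, "b", "left")
  vals <- connValues(connr)[4:6, 4:6]
  vals <- sort(vals[upper.tri(vals)])
  expect_equal(mcr$within, vals[2])

  bad_map <- new("ParcellationMap", entries = mapEntries(mapr)[-1, ])
  expect_error(medianConnectivity(connr, bad_map, "b", "left"), "P0001")
})

test_that("all-scale computation is consistent with standalone metrics", {
  set.seed(60)
  ## two disconnected planted networks
  w <- matrix(0, 8, 8)
  w[1:4, 1:4] <- symRand(4, p = 0.9)[, ]
  w[5:8, 5:8] <- symRand(4, p = 0.9)[, ]
  diag(w) <- 0
  ids <- sprintf("P%04d", 1:8)
  dimnames(w) <- list(ids, ids)
  adj <- makeAdj(w)
  map <- new("ParcellationMap", entries = data.frame(
    parcel_id = ids, network = rep(c("a", "b"), each = 4),
    hemisphere = "left", stringsAsFactors = FALSE))
  res <- computeAllScales(adj, NULL, map, small_world = FALSE)
  expect_equal(nrow(res$node), 8L)
  row_a <- res$global[res$global$network == "a", ]
  standalone <- makeAdj(w[1:4, 1:4])
  expect_equal(row_a$efficiency, globalEfficiency(standalone))
  expect_equal(row_a$natural_connectivity, naturalConnectivity(standalone))
  expect_equal(row_a$spectral_stability, spectralStability(standalone))

  ## a single network covering the whole graph reproduces the whole-brain row
  map1 <- new("ParcellationMap", entries = data.frame(
    parcel_id = ids, network = "all", hemisphere = "left",
    stringsAsFactors = FALSE))
  res1 <- computeAllScales(adj, NULL, map1, small_world = FALSE)
  wb <- res1$global[res1$global$network == "whole_brain", ]
  net <- res1$global[res1$global$network == "all", ]
  for (cl in c("efficiency", "modularity", "global_clustering",
               "natural_connectivity", "spectral_stability"))
    expect_equal(wb[[cl]], net[[cl]])

  ## a parcel missing from the map is an error naming it
  expect_error(computeAllScales(adj, NULL,
    new("ParcellationMap", entries = mapEntries(map)[-3, ]),
    small_world = FALSE), "P0003")
})

test_that("global metrics are invariant and node metrics equivariant under relabeling", {
  set.seed(70)
  w <- symRand(8, p = 0.6)
  ids <- sprintf("P%04d", 1:8)
  dimnames(w) <- list(ids, ids)
  perm <- sample(8)
  wp <- w[perm, perm]
  a1 <- makeAdj(w); a2 <- makeAdj(wp)
  expect_equal(globalEfficiency(a1), globalEfficiency(a2), tolerance = 1e-12)
  expect_equal(globalClustering(a1), globalClustering(a2), tolerance = 1e-12)
  expect_equal(naturalConnectivity(a1), naturalConnectivity(a2), tolerance = 1e-10)
  expect_equal(spectralStability(a1), spectralStability(a2), tolerance = 1e-10)
  expect_equal(eigenvectorCentrality(a1)[rownames(wp)],
               eigenvectorCentrality(a2), tolerance = 1e-6)
  expect_identical(nodeDegree(a1)[rownames(wp)], nodeDegree(a2))
})

test_that("adding an edge never decreases the spectral robustness metrics", {
  set.seed(80)
  for (k in 1:5) {
    w <- symRand(7, p = 0.4)
    zero <- which(w == 0 & upper.tri(w), arr.ind = TRUE)
    if (nrow(zero) == 0) next
    pick <- zero[sample(nrow(zero), 1), ]
    w2 <- w
    w2[pick[1], pick[2]] <- w2[pick[2], pick[1]] <- runif(1, 0.2, 1)
    expect_gte(naturalConnectivity(makeAdj(w2)),
               naturalConnectivity(makeAdj(w)) - 1e-12)
    expect_gte(spectralStability(makeAdj(w2)),
               spectralStability(makeAdj(w)) - 1e-12)
  }
})

test_that("weaker within-network synchrony lowers the targeted network's topology", {
  mkcfg <- function(rw, seed) cohortConfig(
    n_subjects = 8L, n_parcels = 64L, n_timepoints = 250L,
    n_runs_per_subject = 1L, rho_within = rw, rho_between = 0.05,
    belief_topology_d = 0, subject_sd = 0.02, seed = seed)
  netMeans <- function(cfg) {
    rec <- generateBeliefs(generateCovariates(cfg), cfg)
    map <- parcellationFromLayout(cfg)
    rows <- lapply(seq_len(nrow(rec)), function(i) {
      ts <- generateTimeSeries(rec[i, , drop = FALSE], cfg)[[1]]
      conn <- peakCrossCorr(ts, max_lag = 0)
      adj <- applyThreshold(conn, 0.25)
      g <- computeAllScales(adj, conn, map, small_world = FALSE)$global
      g[g$network == cfg@target_network & g$hemisphere == cfg@target_hemisphere, ]
    })
    colMeans(do.call(rbind, rows)[, c("efficiency", "global_clustering",
                                      "natural_connectivity",
                                      "spectral_stability")])
  }
  hi <- netMeans(mkcfg(0.55, 91L))
  lo <- netMeans(mkcfg(0.35, 91L))
  expect_true(all(lo <= hi))
})
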