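## Global and nodal topological properties of thresholded connectivity
## graphs, at three spatial scales: whole brain, (network, hemisphere)
## induced subgraphs, and individual nodes. The undefined-marker for
## metrics that do not exist on a given graph (e.g. clustering with no
## connected triples) is NA, never a silent zero.

.adjGraph <- function(w, weighted = TRUE) {
  igraph::graph_from_adjacency_matrix(
    w, mode = "undirected", weighted = if (weighted) TRUE else NULL,
    diag = FALSE)
}

.weightsOf <- function(adj, binary) {
  if (binary) binarizedView(adj) else adjWeights(adj)
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest-path distance, with
#' edge lengths 1/weight (hop counts on the binary view). Unreachable pairs
#' contribute zero, so an edgeless graph has efficiency 0.
#'
#' @param adj an \code{\linkS4class{AdjacencyMatrix}}.
#' @param binary use the binary view (hop-count distances).
#' @return efficiency in [0, Inf); NA for graphs with fewer than 2 nodes.
#' @export
globalEfficiency <- function(adj, binary = FALSE) {
  w <- .weightsOf(adj, binary)
  n <- nrow(w)
  if (n < 2L) return(NA_real_)
  g <- .adjGraph(w)
  if (igraph::ecount(g) == 0L) return(0)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Global clustering (transitivity)
#'
#' 3 x triangles / connected triples on the binary view.
#'
#' @param adj an \code{\linkS4class{AdjacencyMatrix}}.
#' @return transitivity in [0, 1]; NA when the graph has no connected
#'   triples (or fewer than 3 nodes).
#' @export
globalClustering <- function(adj) {
  w <- binarizedView(adj)
  if (nrow(w) < 3L) return(NA_real_)
  tr <- igraph::transitivity(.adjGraph(w, weighted = FALSE), type = "global")
  if (is.nan(tr)) NA_real_ else tr
}

#' Local clustering coefficients
#'
#' Per-node triangle density among neighbours on the binary view (nodes of
#' degree < 2 get 0); with \code{weighted = TRUE} the geometric-mean
#' (Onnela) weighted variant on weights rescaled by the maximum.
#'
#' @param adj an \code{\linkS4class{AdjacencyMatrix}}.
#' @param weighted use the geometric-mean weighted variant.
#' @return named numeric vector, one coefficient per node.
#' @export
localClustering <- function(adj, weighted = FALSE) {
  b <- binarizedView(adj)
  k <- rowSums(b)
  if (!weighted) {
    cc <- igraph::transitivity(.adjGraph(b, weighted = FALSE),
                               type = "localundirected")
  } else {
    w <- adjWeights(adj)
    mx <- max(w)
    wh <- if (mx > 0) (w / mx)^(1 / 3) else w
    cc <- diag(wh %*% wh %*% wh) / (k * (k - 1))
  }
  cc[!is.finite(cc)] <- 0
  cc[k < 2] <- 0
  names(cc) <- rownames(b)
  cc
}

## weighted Newman-Girvan modularity of a partition
.partitionQ <- function(w, membership) {
  two_m <- sum(w)
  k <- rowSums(w)
  q <- 0
  for (cc in unique(membership)) {
    inc <- membership == cc
    q <- q + sum(w[inc, inc]) / two_m - (sum(k[inc]) / two_m)^2
  }
  q
}

## enumerate all set partitions (restricted growth strings) of n items
.allPartitions <- function(n) {
  parts <- list(1L)
  if (n > 1) for (i in 2:n) {
    parts <- unlist(lapply(parts, function(p) {
      lapply(seq_len(max(p) + 1L), function(b) c(p, b))
    }), recursive = FALSE)
  }
  parts
}

#' Community structure by modularity maximization
#'
#' Maximizes the weighted Newman-Girvan modularity Q. Small graphs (up to
#' \code{exhaustive_max} nodes) are solved exactly by enumerating every
#' partition; larger graphs use greedy multilevel (Louvain) optimization
#' under a fixed local seed and the matrix's node order, so results are
#' deterministic either way.
#'
#' @param adj an \code{\linkS4class{AdjacencyMatrix}}.
#' @param seed integer seed for the Louvain optimizer.
#' @param exhaustive_max largest node count solved by exhaustive search.
#' @return list with \code{membership} (integer vector named by node) and
#'   \code{Q} (the modularity of that partition); both NA for an edgeless
#'   graph.
#' @export
modularityQ <- function(adj, seed = 42L, exhaustive_max = 8L) {
  w <- adjWeights(adj)
  n <- nrow(w)
  if (all(w == 0))
    return(list(membership = rep(NA_integer_, n), Q = NA_real_))
  if (n <= exhaustive_max) {
    parts <- .allPartitions(n)
    qs <- vapply(parts, function(p) .partitionQ(w, p), numeric(1))
    best <- which.max(qs)
    return(list(membership = setNames(parts[[best]], rownames(w)),
                Q = qs[best]))
  }
  g <- .adjGraph(w)
  cl <- withLocalSeed(seed, igraph::cluster_louvain(g, weights = igraph::E(g)$weight))
  mem <- igraph::membership(cl)
  q <- igraph::modularity(g, mem, weights = igraph::E(g)$weight)
  list(membership = setNames(as.integer(mem), rownames(w)), Q = q)
}

#' Small-worldness
#'
#' sigma = (C / C_rand) / (L / L_rand) on the binary view, where C is the
#' global transitivity, L the characteristic path length, and the null
#' values are means over degree-preserving (Maslov-Sneppen) rewired graphs.
#' A disconnected graph is reduced to its largest connected component and
#' the result carries \code{attr(, "largest_component_used") = TRUE}.
#'
#' @param adj an \code{\linkS4class{AdjacencyMatrix}}.
#' @param n_nulls number of rewired null graphs (>= 1).
#' @param seed seed for the rewiring; results are deterministic given it.
#' @return sigma (>= 0), or NA when a null C or L is zero or the component
#'   is too small.
#' @export
smallWorldness <- function(adj, n_nulls = 20L, seed = 1L) {
  if (n_nulls < 1L) stop("n_nulls must be >= 1")
  b <- binarizedView(adj)
  g <- .adjGraph(b, weighted = FALSE)
  flag <- FALSE
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    flag <- TRUE
    keep <- which(comp$membership == which.max(comp$csize))
    g <- igraph::induced_subgraph(g, keep)
  }
  out <- NA_real_
  if (igraph::vcount(g) >= 3L && igraph::ecount(g) >= 2L) {
    C <- igraph::transitivity(g, type = "global")
    L <- igraph::mean_distance(g)
    nulls <- withLocalSeed(seed, lapply(seq_len(n_nulls), function(k) {
      gr <- igraph::rewire(g, igraph::keeping_degseq(
        niter = max(10L * igraph::ecount(g), 100L)))
      c(igraph::transitivity(gr, type = "global"), igraph::mean_distance(gr))
    }))
    nulls <- do.call(rbind, nulls)
    Cr <- mean(nulls[, 1L])
    Lr <- mean(nulls[, 2L])
    if (is.finite(C) && is.finite(Cr) && Cr > 0 && is.finite(Lr) && Lr > 0 &&
        is.finite(L) && L > 0)
      out <- (C / Cr) / (L / Lr)
  }
  attr(out, "largest_component_used") <- flag
  out
}

.symEigen <- function(w) eigen(w, symmetric = TRUE, only.values = TRUE)$values

#' Natural connectivity (topological robustness)
#'
#' ln of the average exponentiated adjacency eigenvalue,
#' ln((1/N) sum_k exp(lambda_k)), computed on the weighted adjacency by
#' default. Evaluated in a max-shifted form for numerical stability.
#'
#' @param adj an \code{\linkS4class{AdjacencyMatrix}}.
#' @param binary compute on the binary view instead.
#' @return natural connectivity (0 for an edgeless graph).
#' @export
naturalConnectivity <- function(adj, binary = FALSE) {
  w <- .weightsOf(adj, binary)
  if (nrow(w) < 1L) return(NA_real_)
  ev <- .symEigen(w)
  m <- max(ev)
  m + log(mean(exp(ev - m)))
}

#' Spectral (topological) stability
#'
#' Largest eigenvalue of the symmetric weighted adjacency matrix.
#'
#' @param adj an \code{\linkS4class{AdjacencyMatrix}}.
#' @return largest eigenvalue (0 for an edgeless graph).
#' @export
spectralStability <- function(adj) {
  w <- adjWeights(adj)
  if (nrow(w) < 1L) return(NA_real_)
  max(.symEigen(w))
}

#' Eigenvector centrality by power iteration
#'
#' Principal eigenvector of the weighted adjacency, computed by shifted
#' power iteration (shift by the maximum weighted degree makes the dominant
#' eigenvalue unique without changing eigenvectors), entries nonnegative
#' and scaled to unit maximum.
#'
#' @param adj an \code{\linkS4class{AdjacencyMatrix}}.
#' @param tol convergence tolerance on the iterate (max-norm).
#' @param max_iter iteration cap.
#' @return named vector scaled to unit maximum; all-NA for an edgeless
#'   graph.
#' @export
eigenvectorCentrality <- function(adj, tol = 1e-10, max_iter = 100000L) {
  w <- adjWeights(adj)
  n <- nrow(w)
  out <- rep(NA_real_, n)
  names(out) <- rownames(w)
  if (all(w == 0)) return(out)
  shift <- max(rowSums(abs(w)))
  a <- w + diag(shift, n)
  v <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    v_new <- a %*% v
    v_new <- v_new / sqrt(sum(v_new^2))
    if (max(abs(v_new - v)) < tol) { v <- v_new; break }
    v <- v_new
  }
  v <- abs(as.numeric(v))
  out[] <- v / max(v)
  out
}

#' Node degree
#'
#' Number of (binary-view) connections incident to each node.
#'
#' @param adj an \code{\linkS4class{AdjacencyMatrix}}.
#' @return named integer vector.
#' @export
nodeDegree <- function(adj) {
  b <- binarizedView(adj)
  setNames(as.integer(rowSums(b)), rownames(b))
}

#' Median connectivity within and outside a network
#'
#' Medians of the raw (pre-threshold, by default) connectivity values over
#' within-network parcel pairs, and over pairs with exactly one endpoint in
#' the network.
#'
#' @param conn a \code{\linkS4class{ConnectivityMatrix}} (or an
#'   \code{\linkS4class{AdjacencyMatrix}} when \code{thresholded = TRUE}
#'   values are wanted).
#' @param map a \code{\linkS4class{ParcellationMap}}.
#' @param network,hemisphere scope selection.
#' @return list with \code{within} (NA for a singleton network) and
#'   \code{outside}.
#' @export
medianConnectivity <- function(conn, map, network, hemisphere) {
  v <- if (is(conn, "ConnectivityMatrix")) connValues(conn) else adjWeights(conn)
  e <- mapEntries(map)
  ids <- rownames(v)
  missing <- setdiff(ids, e$parcel_id)
  if (length(missing) > 0L)
    stop("parcel missing from parcellation map: ", missing[1L])
  sel <- e$parcel_id[e$network == network & e$hemisphere == hemisphere]
  inn <- which(ids %in% sel)
  if (length(inn) == 0L) stop("empty scope: ", network, " / ", hemisphere)
  outn <- setdiff(seq_along(ids), inn)
  within <- if (length(inn) < 2L) NA_real_ else {
    sub <- v[inn, inn, drop = FALSE]
    median(sub[upper.tri(sub)])
  }
  outside <- if (length(outn) == 0L) NA_real_ else
    median(as.numeric(v[inn, outn, drop = FALSE]))
  list(within = within, outside = outside)
}

.globalRow <- function(adj, conn, map, network, hemisphere, n_nulls, seed,
                       small_world) {
  sw <- if (small_world) as.numeric(smallWorldness(adj, n_nulls, seed)) else NA_real_
  mc <- if (!is.null(conn) && !is.null(map) && !is.na(network))
    medianConnectivity(conn, map, network, hemisphere)
  else list(within = NA_real_, outside = NA_real_)
  mq <- modularityQ(adj)
  data.frame(
    network = if (is.na(network)) "whole_brain" else network,
    hemisphere = if (is.na(network)) "both" else hemisphere,
    n_nodes = nrow(adjWeights(adj)),
    efficiency = globalEfficiency(adj),
    modularity = mq$Q,
    global_clustering = globalClustering(adj),
    small_worldness = sw,
    natural_connectivity = naturalConnectivity(adj),
    spectral_stability = spectralStability(adj),
    median_conn_in = mc$within,
    median_conn_out = mc$outside,
    stringsAsFactors = FALSE)
}

#' Topological properties at all three spatial scales
#'
#' Global metrics for the whole brain and for every (network, hemisphere)
#' induced subgraph, plus node metrics (eigenvector centrality on the
#' whole-brain graph, degree, local clustering) for every parcel. Row order
#' is deterministic: whole brain first, then networks in map order.
#'
#' @param adj whole-brain \code{\linkS4class{AdjacencyMatrix}}.
#' @param conn the pre-threshold \code{\linkS4class{ConnectivityMatrix}}
#'   (for median connectivity); may be NULL.
#' @param map a \code{\linkS4class{ParcellationMap}} covering every parcel.
#' @param n_nulls,seed small-worldness null controls.
#' @param small_world compute small-worldness (the slowest metric); off by
#'   default at the network scale loop when FALSE.
#' @return list with data.frames \code{global} and \code{node}.
#' @export
computeAllScales <- function(adj, conn, map, n_nulls = 20L, seed = 1L,
                             small_world = TRUE) {
  w <- adjWeights(adj)
  ids <- rownames(w)
  e <- mapEntries(map)
  missing <- setdiff(ids, e$parcel_id)
  if (length(missing) > 0L)
    stop("parcel missing from parcellation map: ", missing[1L])
  scopes <- unique(e[e$parcel_id %in% ids, c("network", "hemisphere")])
  global <- .globalRow(adj, conn, map, NA, NA, n_nulls, seed, small_world)
  for (k in seq_len(nrow(scopes))) {
    sel <- e$parcel_id[e$network == scopes$network[k] &
                       e$hemisphere == scopes$hemisphere[k]]
    inn <- which(ids %in% sel)
    sub_adj <- new("AdjacencyMatrix",
                   weights = w[inn, inn, drop = FALSE],
                   thresholdUsed = thresholdUsed(adj))
    global <- rbind(global, .globalRow(
      sub_adj, conn, map, scopes$network[k], scopes$hemisphere[k],
      n_nulls, seed, small_world))
  }
  rownames(global) <- NULL
  node <- data.frame(
    parcel_id = ids,
    eigenvector_centrality = as.numeric(eigenvectorCentrality(adj)),
    degree = as.integer(nodeDegree(adj)),
    local_clustering = as.numeric(localClustering(adj)),
    stringsAsFactors = FALSE)
  list(global = global, node = node)
}
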