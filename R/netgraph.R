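#' Build a weighted undirected graph from a thresholded connectivity matrix
#'
#' Edge weight equals the correlation where it reaches the per-matrix FDR
#' cutoff; everything else (including every negative correlation) is zero,
#' and the diagonal is zeroed -- the weighted-undirected-network construction
#' used for functional MRI graphs.
#'
#' @param result an `fc_result` from [partial_corr_matrix()].
#' @return An object of class `fc_graph`: `weights` (symmetric non-negative
#'   matrix, zero diagonal) and `node_labels`.
#' @export
build_adjacency <- function(result) {
  if (is.null(result$fdr_cutoff)) stop("fdr_cutoff not computed")
  w <- result$r
  w[!(w >= result$fdr_cutoff & w > 0)] <- 0
  diag(w) <- 0
  structure(list(weights = w,
                 node_labels = result$roi_labels %||%
                   rownames(result$r) %||%
                   sprintf("ROI%03d", seq_len(nrow(w)))),
            class = "fc_graph")
}

#' Construct an fc_graph directly from a weight matrix
#'
#' @param weights symmetric non-negative matrix with zero diagonal.
#' @param node_labels optional labels.
#' @return An `fc_graph`.
#' @export
fc_graph <- function(weights, node_labels = NULL) {
  weights <- as.matrix(weights)
  stopifnot(isSymmetric(weights, tol = 1e-10), all(weights >= 0))
  diag(weights) <- 0
  structure(list(weights = weights,
                 node_labels = node_labels %||%
                   sprintf("N%03d", seq_len(nrow(weights)))),
            class = "fc_graph")
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Newman weighted modularity maximized by Louvain with restarts
#'
#' Runs the Louvain community-detection algorithm `n_restarts` times under
#' random node orders and returns the best weighted modularity Q and its
#' partition. Deterministic given the seed.
#'
#' @param g an `fc_graph`.
#' @param n_restarts number of random-order restarts (default 100).
#' @param resolution Louvain resolution parameter (default 1).
#' @param seed integer seed.
#' @return List with `q` (modularity) and `partition` (integer labels per
#'   node, in the original node order).
#' @export
graph_modularity <- function(g, n_restarts = 100, resolution = 1, seed = 1) {
  ig <- as_igraph(g)
  if (igraph::ecount(ig) == 0) {
    stop("modularity is undefined for an edgeless graph")
  }
  n <- igraph::vcount(ig)
  with_seed(seed, {
    best_q <- -Inf
    best_mem <- NULL
    for (k in seq_len(n_restarts)) {
      perm <- sample.int(n)
      gp <- igraph::permute(ig, perm)
      cl <- igraph::cluster_louvain(gp, resolution = resolution)
      qk <- igraph::modularity(gp, igraph::membership(cl),
                               weights = igraph::E(gp)$weight)
      if (qk > best_q) {
        best_q <- qk
        best_mem <- igraph::membership(cl)[perm]
      }
    }
    list(q = best_q, partition = as.integer(best_mem))
  })
}

#' All-pairs shortest path lengths
#'
#' Edge length is the reciprocal of the weight (strong connections are
#' short); lengths are summed along paths (Dijkstra) and unreachable pairs
#' are `Inf`.
#'
#' @param g an `fc_graph`.
#' @param weight_to_length `"inverse"` (default, length = 1/w) or `"neglog"`
#'   (length = -log(w), for weights in (0, 1]).
#' @return Symmetric matrix of path lengths (0 on the diagonal).
#' @export
shortest_path_lengths <- function(g, weight_to_length = c("inverse",
                                                          "neglog")) {
  weight_to_length <- match.arg(weight_to_length)
  ig <- as_igraph(g)
  if (igraph::ecount(ig) == 0) {
    d <- matrix(Inf, nrow(g$weights), nrow(g$weights))
    diag(d) <- 0
    return(d)
  }
  w <- igraph::E(ig)$weight
  len <- if (weight_to_length == "inverse") 1 / w else -log(w)
  if (any(len < 0)) stop("neglog lengths require weights <= 1")
  unname(igraph::distances(ig, weights = len, algorithm = "dijkstra"))
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest path length, with
#' unreachable pairs contributing 0.
#'
#' @param g an `fc_graph`.
#' @param ... passed to [shortest_path_lengths()].
#' @return Scalar efficiency.
#' @export
global_efficiency <- function(g, ...) {
  n <- nrow(g$weights)
  stopifnot(n >= 2)
  d <- shortest_path_lengths(g, ...)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by each
#' node's neighbors (weighted variant); isolated and single-neighbor nodes
#' contribute 0.
#'
#' @param g an `fc_graph`.
#' @param ... passed to [shortest_path_lengths()].
#' @return Scalar efficiency.
#' @export
local_efficiency <- function(g, ...) {
  w <- g$weights
  n <- nrow(w)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    global_efficiency(fc_graph(w[nb, nb, drop = FALSE]), ...)
  }, numeric(1))
  mean(vals)
}

#' Weighted clustering coefficient
#'
#' Geometric-mean triangle intensity: with weights normalized by the graph
#' maximum, node i's coefficient is `sum_jh (w_ij w_ih w_jh)^(1/3) /
#' (k_i (k_i - 1))`; nodes of degree < 2 contribute 0. Returns the mean over
#' nodes.
#'
#' @param g an `fc_graph`.
#' @return Scalar clustering coefficient.
#' @export
clustering_coefficient <- function(g) {
  w <- g$weights
  if (max(w) == 0) return(0)
  wn <- (w / max(w))^(1 / 3)
  num <- diag(wn %*% wn %*% wn)
  k <- rowSums(w > 0)
  ci <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  mean(ci)
}

#' Characteristic path length
#'
#' Mean of the finite off-diagonal shortest path lengths; infinite
#' (unreachable) entries are excluded and their count reported as attribute
#' `n_infinite`.
#'
#' @param g an `fc_graph`.
#' @param ... passed to [shortest_path_lengths()].
#' @return Scalar path length with attribute `n_infinite`.
#' @export
characteristic_path_length <- function(g, ...) {
  d <- shortest_path_lengths(g, ...)
  off <- d[row(d) != col(d)]
  finite <- off[is.finite(off)]
  if (!length(finite)) stop("no finite pairwise distances")
  structure(mean(finite), n_infinite = sum(!is.finite(off)))
}

#' All graph metrics at once
#'
#' @param g an `fc_graph`.
#' @param n_restarts,resolution,seed passed to [graph_modularity()].
#' @return List with `modularity_q`, `global_efficiency`,
#'   `local_efficiency`, `clustering`, `char_path_length`.
#' @export
graph_metrics <- function(g, n_restarts = 100, resolution = 1, seed = 1) {
  list(modularity_q = graph_modularity(g, n_restarts, resolution, seed)$q,
       global_efficiency = global_efficiency(g),
       local_efficiency = local_efficiency(g),
       clustering = clustering_coefficient(g),
       char_path_length = as.numeric(characteristic_path_length(g)))
}
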