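#' Normalize a parameter to a 0-1 risk-prediction score
#'
#' Min-max normalization oriented by the sign of the parameter's correlation
#' with the ground-truth risk score: z = (y - min)/(max - min) when r >= 0,
#' and 1 - (y - min)/(max - min) when r < 0, so 0 always means low risk and 1
#' high risk. Invariant under positive affine transforms of `y`.
#'
#' @param y parameter values across patients (non-constant).
#' @param ground_truth continuous risk scores (used only for the sign of r),
#'   or a precomputed correlation via `r`.
#' @param r optional correlation coefficient overriding the computation.
#' @return Numeric vector in [0,1].
#' @export
risk_normalize <- function(y, ground_truth = NULL, r = NULL) {
  rng <- range(y)
  if (rng[2] <= rng[1]) stop("constant parameter has no risk orientation")
  if (is.null(r)) {
    if (is.null(ground_truth)) stop("supply ground_truth or r")
    r <- stats::cor(y, ground_truth)
  }
  z <- (y - rng[1]) / (rng[2] - rng[1])
  if (r < 0) z <- 1 - z
  z
}

#' Build the parameter interaction network
#'
#' Vertices are the K clinical/imaging parameters; the full edge weight
#' matrix is E_ij = 1 - corr(z_i, z_j) (Pearson) over the risk-score rows,
#' so weights lie in [0,2] and act as distances. Each vertex keeps edges to
#' its k smallest-weight neighbors and the k-NN digraph is union-symmetrized
#' (an edge survives if either endpoint selects it).
#'
#' @param Z K x n matrix of risk-prediction scores (rows = parameters,
#'   typically from [risk_normalize()]), with rownames as parameter names.
#' @param k neighborhood size (default 3; must be < K).
#' @return An object of class `informatics_network`: list with `graph`
#'   (igraph, weighted undirected), `E` (full weight matrix), `k`.
#' @export
build_network <- function(Z, k = 3L) {
  Z <- as.matrix(Z)
  K <- nrow(Z)
  if (K < 2L) stop("need K >= 2 parameters")
  if (k >= K) stop("k must be smaller than the number of parameters")
  if (any(apply(Z, 1L, stats::sd) == 0)) stop("constant risk-score row")
  if (is.null(rownames(Z))) rownames(Z) <- paste0("P", seq_len(K))
  E <- 1 - stats::cor(t(Z))
  diag(E) <- 0
  A <- matrix(0, K, K, dimnames = list(rownames(Z), rownames(Z)))
  for (i in seq_len(K)) {
    w <- E[i, ]
    w[i] <- Inf
    nn <- order(w)[seq_len(k)]
    A[i, nn] <- 1
  }
  keep <- (A + t(A)) > 0               # union symmetrization
  W <- E * keep
  # igraph drops zero-weight edges from adjacency matrices; perfectly
  # correlated parameters (weight 0) still need an edge, so nudge weights by
  # a representable floor while keeping the stored E exact.
  Wg <- ifelse(keep, pmax(W, 1e-12), 0)
  g <- igraph::graph_from_adjacency_matrix(Wg, mode = "undirected",
                                           weighted = TRUE)
  structure(list(graph = g, E = E, keep = keep, k = k,
                 names = rownames(Z)),
            class = "informatics_network")
}

#' @export
print.informatics_network <- function(x, ...) {
  cat(sprintf("Parameter interaction network: %d vertices, %d edges (k = %d)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$k))
  invisible(x)
}

# Largest connected component (vertex ids), with a flag if the graph was cut.
largest_component <- function(g) {
  comp <- igraph::components(g)
  flag <- comp$no > 1L
  vids <- which(comp$membership == which.max(comp$csize))
  list(graph = igraph::induced_subgraph(g, vids), flagged = flag, vids = vids)
}

#' Path-length metrics of the network
#'
#' Weighted shortest paths over all unordered vertex pairs: the average path
#' length is their mean and the diameter their maximum. On a disconnected
#' graph the metrics are computed over the largest component and flagged.
#'
#' @param network an [build_network()] result.
#' @return list with `average_path_length`, `diameter`, `flagged`.
#' @export
path_metrics <- function(network) {
  lc <- largest_component(network$graph)
  d <- igraph::distances(lc$graph)
  ut <- d[upper.tri(d)]
  if (length(ut) == 0L) stop("empty graph")
  list(average_path_length = mean(ut), diameter = max(ut),
       flagged = lc$flagged)
}

#' Clustering coefficient and Erdos-Renyi baseline
#'
#' Unweighted local clustering coefficients averaged over vertices (vertices
#' of degree < 2 count 0), compared against the expected clustering
#' coefficient of a G(n, p) random graph matched on vertex and edge count,
#' which is its edge density p.
#'
#' @param network an [build_network()] result.
#' @return list with `average_clustering`, `er_baseline`.
#' @export
clustering_stats <- function(network) {
  g <- network$graph
  if (igraph::vcount(g) < 3L) stop("need >= 3 vertices")
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cc[is.na(cc)] <- 0
  n <- igraph::vcount(g)
  list(average_clustering = mean(cc),
       er_baseline = igraph::ecount(g) / (n * (n - 1) / 2))
}

#' Vertex centralities and the integrated centrality
#'
#' Degree (neighbor count), betweenness (weighted shortest-path pair counts
#' through the vertex; raw and normalized by (K-1)(K-2)/2) and harmonic
#' centrality (sum of reciprocal weighted distances to all other vertices).
#' The integrated centrality is the mean of the three after min-max
#' normalization of each metric to [0,1] across vertices.
#'
#' @param network an [build_network()] result.
#' @return data.frame (parameter, degree, betweenness, betweenness_norm,
#'   harmonic, integrated) in vertex order.
#' @export
centralities <- function(network) {
  g <- network$graph
  K <- igraph::vcount(g)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, weights = igraph::E(g)$weight)
  har <- igraph::harmonic_centrality(g, weights = igraph::E(g)$weight)
  mm <- function(x) {
    s <- max(x) - min(x)
    if (s == 0) rep(0.5, length(x)) else (x - min(x)) / s
  }
  integ <- (mm(deg) + mm(btw) + mm(har)) / 3
  data.frame(parameter = network$names,
             degree = as.numeric(deg),
             betweenness = as.numeric(btw),
             betweenness_norm = as.numeric(btw) / ((K - 1) * (K - 2) / 2),
             harmonic = as.numeric(har),
             integrated = as.numeric(integ),
             stringsAsFactors = FALSE)
}

#' Hub parameters of the network
#'
#' Parameters ranked by integrated centrality (descending), ties broken
#' alphabetically by name (logged via a message).
#'
#' @param report a [centralities()] data.frame.
#' @param top_m how many hubs to return.
#' @return The top rows of the report in hub order.
#' @export
hub_nodes <- function(report, top_m = 10L) {
  if (top_m > nrow(report)) stop("top_m exceeds the number of parameters")
  if (anyDuplicated(report$integrated)) message("integrated-centrality tie; breaking by name")
  ord <- order(-report$integrated, report$parameter)
  report[ord[seq_len(top_m)], , drop = FALSE]
}
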