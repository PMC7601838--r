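# Isomap: k-nearest-neighbor graph on Euclidean distances, geodesic
# (shortest-path) distances, classical MDS. Authored here because the
# out-of-sample extension below must share the fitted eigensystem.

isomap_fit <- function(X, k, d_out = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 1L || k >= n) stop("need 1 <= k < n")
  if (n < d_out + 1L) stop("need n >= d_out + 1")
  D <- as.matrix(stats::dist(X))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nn <- order(D[i, ])[2:(k + 1L)]   # self excluded; ties by index (deterministic)
    A[i, nn] <- D[i, nn]
  }
  A <- pmax(A, t(A))                  # union symmetrization of the k-NN digraph
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected", weighted = TRUE)
  geo <- igraph::distances(g, algorithm = "dijkstra")
  if (any(!is.finite(geo)))
    stop("disconnected neighborhood graph")
  G2 <- geo^2
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% G2 %*% J
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- which(eig$values > .Machine$double.eps * max(abs(eig$values)) * n)
  if (length(pos) < d_out) d_out <- max(1L, length(pos))
  lambda <- eig$values[seq_len(d_out)]
  V <- eig$vectors[, seq_len(d_out), drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (a in seq_len(d_out)) {
    imax <- which.max(abs(V[, a]))
    if (V[imax, a] < 0) V[, a] <- -V[, a]
  }
  Y <- sweep(V, 2L, sqrt(pmax(lambda, 0)), `*`)
  knn_radius <- max(A[A > 0])
  list(X = X, Y = Y, k = k, d_out = d_out, lambda = lambda, V = V,
       geo_colmeans = colMeans(G2), geo = geo, knn_radius = knn_radius)
}

# Nystrom-style out-of-sample extension: geodesic distances from a new point
# approximated through its k nearest training neighbors, then projected with
# the stored MDS eigensystem. A training point re-transformed reproduces its
# stored embedding exactly. Points with no training neighbor within the
# largest training k-NN edge length are flagged and fall back to their
# nearest training point's embedding.
isomap_transform <- function(fit, Xnew) {
  Xnew <- as.matrix(Xnew)
  if (ncol(Xnew) != ncol(fit$X)) stop("row length mismatch with training space")
  n <- nrow(fit$X)
  out <- matrix(NA_real_, nrow(Xnew), fit$d_out)
  fallback <- logical(nrow(Xnew))
  for (r in seq_len(nrow(Xnew))) {
    dx <- sqrt(colSums((t(fit$X) - Xnew[r, ])^2))
    if (min(dx) > fit$knn_radius) {
      fallback[r] <- TRUE
      out[r, ] <- fit$Y[which.min(dx), ]
      next
    }
    nn <- order(dx)[seq_len(min(fit$k, n))]
    dgeo <- apply(fit$geo[nn, , drop = FALSE] + dx[nn], 2L, min)
    y <- as.vector(crossprod(fit$V, fit$geo_colmeans - dgeo^2)) /
      (2 * sqrt(pmax(fit$lambda, .Machine$double.eps)))
    out[r, ] <- y
  }
  attr(out, "fallback") <- fallback
  out
}
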