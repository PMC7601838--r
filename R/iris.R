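#' Enumerate 1- to 3-parameter subspaces
#'
#' All combinations of one, two or three parameters out of `D`, giving
#' C(D,1) + C(D,2) + C(D,3) unique index sets in a deterministic order
#' (increasing size, then lexicographic).
#'
#' @param D number of parameters (>= 1).
#' @param d_max largest subspace size (default 3).
#' @return List of integer index vectors.
#' @export
enumerate_subspaces <- function(D, d_max = 3L) {
  if (D < 1L) stop("D must be >= 1")
  out <- list()
  for (d in seq_len(min(d_max, D))) {
    cmb <- utils::combn(D, d)
    out <- c(out, lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
  }
  out
}

#' Embed one subspace to a 1-D manifold coordinate
#'
#' Columns are z-score standardized, a k-nearest-neighbor graph is built on
#' Euclidean distances, geodesic distances are taken along the graph, and the
#' first classical-MDS coordinate of the geodesic distance matrix is
#' returned. Deterministic given its input (sign fixed so the
#' largest-magnitude loading is positive). A disconnected neighborhood graph
#' raises an error, which the multi-subspace driver records and skips.
#'
#' @param S matrix (patients x d) of the subspace slice, d in 1..3.
#' @param k_nldr neighborhood size (default 10; capped at n-1).
#' @return Numeric length-n embedding with attribute `fit` (the reusable
#'   transform for out-of-sample points).
#' @export
embed_subspace <- function(S, k_nldr = 10L) {
  S <- as.matrix(S)
  n <- nrow(S)
  k <- min(k_nldr, n - 1L)
  ctr <- colMeans(S)
  scl <- apply(S, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Z <- scale(S, center = ctr, scale = scl)
  fit <- isomap_fit(Z, k = k, d_out = 1L)
  y <- fit$Y[, 1L]
  fit$center <- ctr; fit$scale <- scl
  attr(y, "fit") <- fit
  y
}

#' Gate embeddings by correlation with the ground truth
#'
#' Pearson correlation R_i of every embedding with the continuous risk score;
#' embeddings with |R_i| >= threshold are retained and sign-aligned so that
#' the retained R_i are positive (1-D embeddings have arbitrary sign).
#' Zero-variance embeddings have undefined correlation and are excluded.
#'
#' @param embeddings list of length-n numeric embeddings (as from
#'   [embed_subspace()]), or an n x m matrix.
#' @param ground_truth length-n continuous risk score.
#' @param threshold retention threshold on |R| (default 0.5).
#' @return An object of class `embedding_set`: list with `U` (n x m matrix of
#'   retained, sign-aligned embeddings), `R` (their correlations, all >= 0),
#'   `index` (positions retained in the input), `R_all`, `flipped`,
#'   `excluded` (zero-variance positions).
#' @export
score_and_select <- function(embeddings, ground_truth, threshold = 0.5) {
  if (is.matrix(embeddings))
    embeddings <- lapply(seq_len(ncol(embeddings)), function(j) embeddings[, j])
  n <- length(ground_truth)
  if (any(vapply(embeddings, length, 1L) != n))
    stop("embeddings and ground truth differ in length")
  R_all <- vapply(embeddings, function(y) {
    if (stats::sd(y) == 0) return(NA_real_)
    stats::cor(y, ground_truth)
  }, numeric(1L))
  excluded <- which(is.na(R_all))
  keep <- which(!is.na(R_all) & abs(R_all) >= threshold)
  flipped <- R_all[keep] < 0
  U <- vapply(seq_along(keep), function(j) {
    y <- as.numeric(embeddings[[keep[j]]])
    if (flipped[j]) -y else y
  }, numeric(n))
  if (length(keep)) U <- matrix(U, nrow = n) else U <- matrix(numeric(0), nrow = n, ncol = 0)
  structure(list(U = U, R = abs(R_all[keep]), index = keep, R_all = R_all,
                 flipped = flipped, excluded = excluded, threshold = threshold),
            class = "embedding_set")
}

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("Embedding set: %d retained of %d (|R| >= %.2f)\n",
              length(x$index), length(x$R_all), x$threshold))
  invisible(x)
}

#' Parameter importance from the retained embedding set
#'
#' Importance of parameter i = 100 x (number of retained embeddings whose
#' subspace contains i) / (number retained). Parameters at 0 are candidates
#' to discard.
#'
#' @param embedding_set an [score_and_select()] result.
#' @param subspaces the full subspace list the embeddings came from.
#' @param D number of parameters.
#' @param names optional parameter names.
#' @return data.frame (parameter, importance) sorted by decreasing
#'   importance, ties broken by parameter name.
#' @export
feature_importance <- function(embedding_set, subspaces, D, names = NULL) {
  if (length(embedding_set$index) == 0L) stop("empty embedding set")
  if (is.null(names)) names <- paste0("P", seq_len(D))
  used <- subspaces[embedding_set$index]
  imp <- vapply(seq_len(D), function(i)
    100 * sum(vapply(used, function(s) i %in% s, logical(1L))) / length(used),
    numeric(1L))
  out <- data.frame(parameter = names, importance = imp,
                    stringsAsFactors = FALSE)
  out[order(-out$importance, out$parameter), , drop = FALSE]
}

#' Hierarchical clustering heatmap model of the retained embeddings
#'
#' Columns (embeddings) are min-max scaled to [0,1] and clustered with
#' average-linkage agglomeration on correlation distance (1 - r); rows
#' (patients) are clustered on Euclidean distance over the scaled matrix.
#' Patient risk clusters come from cutting the row dendrogram (default 3
#' groups). Duplicate embeddings merge at height 0, identifying redundancy.
#'
#' @param embedding_set an [score_and_select()] result with >= 2 retained
#'   embeddings.
#' @param n_clusters number of patient clusters to cut (default 3).
#' @return An object of class `heatmap_model`: scaled matrix `U01`, scaling
#'   ranges, row/column `hclust` trees, `clusters` (patient labels) and
#'   `centroids` (cluster means in scaled embedding space).
#' @export
cluster_heatmap <- function(embedding_set, n_clusters = 3L) {
  U <- embedding_set$U
  if (ncol(U) < 2L) stop("need at least 2 retained embeddings")
  if (nrow(U) < 2L) stop("need at least 2 patients")
  rng <- apply(U, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  if (all(span == 0)) stop("degenerate (constant) embedding matrix")
  span[span == 0] <- 1
  U01 <- sweep(sweep(U, 2L, rng[1L, ]), 2L, span, `/`)
  col_d <- stats::as.dist(1 - stats::cor(U01))
  row_h <- stats::hclust(stats::dist(U01), method = "average")
  col_h <- stats::hclust(col_d, method = "average")
  clusters <- stats::cutree(row_h, k = min(n_clusters, nrow(U)))
  centroids <- do.call(rbind, lapply(sort(unique(clusters)), function(g)
    colMeans(U01[clusters == g, , drop = FALSE])))
  structure(list(U01 = U01, range_lo = rng[1L, ], range_span = span,
                 row_hclust = row_h, col_hclust = col_h,
                 clusters = clusters, centroids = centroids),
            class = "heatmap_model")
}

#' Assign a patient row in scaled embedding space to a risk cluster
#'
#' Nearest-centroid assignment; ties go to the lower-index cluster (logged
#' via a message).
#'
#' @param heatmap_model a [cluster_heatmap()] model.
#' @param new_row numeric vector in the scaled embedding space (same length
#'   as `ncol(U01)`).
#' @return Integer cluster label.
#' @export
assign_patient <- function(heatmap_model, new_row) {
  if (length(new_row) != ncol(heatmap_model$U01))
    stop("row length mismatch")
  d2 <- rowSums(sweep(heatmap_model$centroids, 2L, new_row)^2)
  hit <- which(d2 <= min(d2) + .Machine$double.eps * max(1, min(d2)))
  if (length(hit) > 1L) message("centroid tie; assigning lower-index cluster")
  hit[1L]
}

#' Fit the multi-subspace embedding risk model
#'
#' The unsupervised core of the system: every 1-, 2- and 3-parameter
#' subspace of the patient space is embedded to one dimension with Isomap,
#' embeddings correlating with the continuous risk score at |R| >= threshold
#' are retained and sign-aligned, and the retained set is hierarchically
#' clustered in both directions to give the heatmap risk model and patient
#' risk clusters. Missing values are median-imputed before embedding. For
#' D above `prescreen_limit` parameters, enumeration is restricted to the
#' `prescreen_limit` highest-variance parameters.
#'
#' @param X numeric matrix or data.frame, patients x parameters.
#' @param risk length-n continuous ground-truth risk score (e.g. a 0-100
#'   recurrence score).
#' @param threshold correlation gate (default 0.5).
#' @param k_nldr Isomap neighborhood size (default 10).
#' @param d_max largest subspace size (default 3).
#' @param n_clusters patient clusters cut from the row dendrogram (default 3).
#' @param prescreen_limit maximum D enumerated exhaustively (default 25).
#' @return An object of class `radiris` with print, summary, plot and
#'   predict methods.
#' @export
radiris <- function(X, risk, threshold = 0.5, k_nldr = 10L, d_max = 3L,
                    n_clusters = 3L, prescreen_limit = 25L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("P", seq_len(ncol(X)))
  if (nrow(X) != length(risk)) stop("X and risk differ in length")
  med <- apply(X, 2L, stats::median, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- med[j]
  active <- seq_len(ncol(X))
  if (ncol(X) > prescreen_limit) {
    vr <- apply(X, 2L, stats::var)
    active <- sort(order(vr, decreasing = TRUE)[seq_len(prescreen_limit)])
  }
  subspaces <- lapply(enumerate_subspaces(length(active), d_max),
                      function(s) active[s])
  embeddings <- vector("list", length(subspaces))
  failed <- integer(0)
  for (i in seq_along(subspaces)) {
    y <- tryCatch(embed_subspace(X[, subspaces[[i]], drop = FALSE], k_nldr),
                  error = function(e) NULL)
    if (is.null(y)) failed <- c(failed, i) else embeddings[[i]] <- y
  }
  ok <- setdiff(seq_along(subspaces), failed)
  sel <- score_and_select(lapply(embeddings[ok], as.numeric), risk, threshold)
  sel$index <- ok[sel$index]       # back to subspace numbering
  if (length(sel$index) == 0L) {
    warning("no embedding reached the correlation threshold; ",
            "clustering stages unavailable")
    model <- NULL
    importance <- NULL
  } else if (length(sel$index) == 1L) {
    warning("only one retained embedding; heatmap clustering unavailable")
    model <- NULL
    importance <- feature_importance(sel, subspaces, ncol(X), colnames(X))
  } else {
    model <- cluster_heatmap(sel, n_clusters)
    importance <- feature_importance(sel, subspaces, ncol(X), colnames(X))
  }
  structure(list(X = X, risk = risk, medians = med, subspaces = subspaces,
                 fits = lapply(embeddings[sel$index], attr, "fit"),
                 selection = sel, heatmap = model, importance = importance,
                 threshold = threshold, k_nldr = k_nldr,
                 failed_subspaces = failed,
                 parameter_names = colnames(X),
                 call = match.call()),
            class = "radiris")
}

#' @export
print.radiris <- function(x, ...) {
  cat("Multi-subspace embedding risk model\n")
  cat(sprintf("  %d patients, %d parameters, %d subspaces (%d failed)\n",
              nrow(x$X), ncol(x$X), length(x$subspaces),
              length(x$failed_subspaces)))
  cat(sprintf("  retained embeddings: %d (|R| >= %.2f)\n",
              length(x$selection$index), x$threshold))
  if (!is.null(x$heatmap))
    cat(sprintf("  patient clusters: %s\n",
                paste(table(x$heatmap$clusters), collapse = " / ")))
  invisible(x)
}

#' @export
summary.radiris <- function(object, ...) {
  print(object)
  if (!is.null(object$importance)) {
    cat("\nTop parameter importance (% of retained embeddings):\n")
    print(utils::head(object$importance, 10L), row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.radiris <- function(x, ...) {
  if (is.null(x$heatmap)) stop("no heatmap model (no retained embeddings)")
  stats::heatmap(t(x$heatmap$U01),
                 Rowv = stats::as.dendrogram(x$heatmap$col_hclust),
                 Colv = stats::as.dendrogram(x$heatmap$row_hclust),
                 scale = "none", ...)
  invisible(x)
}

#' Classify new patients with a fitted multi-subspace model
#'
#' Each retained subspace embedding is extended to the new rows with the
#' stored out-of-sample Isomap transform, sign-aligned and min-max scaled
#' with the training ranges, and the patient is assigned to the nearest
#' cluster centroid in the scaled embedding space.
#'
#' @param object a fitted [radiris()] model with a heatmap.
#' @param newdata matrix/data.frame of new patient rows over the same
#'   parameters.
#' @param ... unused.
#' @return Integer cluster labels with the scaled embedding coordinates as
#'   attribute `"coords"`.
#' @export
predict.radiris <- function(object, newdata, ...) {
  if (is.null(object$heatmap)) stop("no heatmap model to predict from")
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$X)) stop("row length mismatch")
  for (j in seq_len(ncol(newdata)))
    newdata[is.na(newdata[, j]), j] <- object$medians[j]
  sel <- object$selection
  m <- length(sel$index)
  coords <- matrix(NA_real_, nrow(newdata), m)
  for (jj in seq_len(m)) {
    fit <- object$fits[[jj]]
    cols <- object$subspaces[[sel$index[jj]]]
    Z <- scale(newdata[, cols, drop = FALSE],
               center = fit$center, scale = fit$scale)
    y <- isomap_transform(fit, Z)[, 1L]
    if (sel$flipped[jj]) y <- -y
    coords[, jj] <- (y - object$heatmap$range_lo[jj]) /
      object$heatmap$range_span[jj]
  }
  labels <- apply(coords, 1L, assign_patient, heatmap_model = object$heatmap)
  attr(labels, "coords") <- coords
  labels
}
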