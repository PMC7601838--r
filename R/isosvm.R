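#' Fit a hybrid Isomap + SVM classifier
#'
#' Training features are z-score standardized and embedded to `d_iso`
#' dimensions with Isomap (k_iso-nearest-neighbor graph, geodesic distances,
#' classical MDS); a kernel SVM is trained on the embedding. Class imbalance
#' is handled by multiplying the minority-class misclassification penalty by
#' `ratio` (via class weights). New points are embedded with the stored
#' out-of-sample extension ([isomap_transform()]) before classification.
#'
#' @param x numeric matrix/data.frame of features (n x p).
#' @param y two-level factor (or coercible) of class labels; the second
#'   level is treated as the positive class for decision values.
#' @param k_iso Isomap neighborhood size (default 60; internally capped at
#'   n - 2 so subgroup fits remain feasible).
#' @param d_iso embedding dimensionality (default 10; requires
#'   k_iso >= d_iso + 1).
#' @param ratio minority-class penalty multiplier (>= 1, default 2 as in a
#'   2:1 imbalance penalty).
#' @param kernel SVM kernel, `"radial"` (default) or `"linear"`.
#' @param cost base SVM cost (default 1).
#' @param weight_class which class receives the penalty multiplier; defaults
#'   to the minority class of `y`. Cross-validation loops must fix this once
#'   on the full data: re-deriving it inside each fold would tie the penalty
#'   to the held-out sample's class and bias the decision values.
#' @return An object of class `isosvm` with `predict` support returning
#'   decision values or labels.
#' @export
isosvm <- function(x, y, k_iso = 60L, d_iso = 10L, ratio = 2,
                   kernel = c("radial", "linear"), cost = 1,
                   weight_class = NULL) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) != 2L) stop("need exactly 2 classes")
  if (any(table(y) < 2L)) stop("each class needs >= 2 members")
  if (ratio < 1) stop("imbalance ratio must be >= 1")
  n <- nrow(x)
  k_eff <- min(k_iso, n - 2L)
  if (k_eff < d_iso + 1L)
    stop("config error: k_iso must be >= d_iso + 1")
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  z <- scale(x, center = ctr, scale = scl)
  fit <- isomap_fit(z, k = k_eff, d_out = d_iso)
  emb <- fit$Y
  colnames(emb) <- paste0("iso", seq_len(ncol(emb)))
  minority <- if (is.null(weight_class)) names(which.min(table(y))) else
    match.arg(weight_class, levels(y))
  cw <- stats::setNames(c(1, 1), levels(y))
  cw[minority] <- ratio
  svm_fit <- e1071::svm(emb, y, kernel = kernel, cost = cost,
                        class.weights = cw, scale = FALSE)
  structure(list(iso = fit, svm = svm_fit, center = ctr, scale = scl,
                 levels = levels(y), minority = minority,
                 k_iso = k_iso, k_eff = k_eff, d_iso = ncol(emb),
                 ratio = ratio, kernel = kernel, cost = cost,
                 call = match.call()),
            class = "isosvm")
}

#' @export
print.isosvm <- function(x, ...) {
  cat(sprintf("Isomap+SVM classifier: k = %d (requested %d), d = %d, %s kernel, penalty ratio %g:1 on '%s'\n",
              x$k_eff, x$k_iso, x$d_iso, x$kernel, x$ratio, x$minority))
  invisible(x)
}

#' Embed out-of-sample points with a fitted classifier's manifold transform
#'
#' @param model a fitted [isosvm()] model.
#' @param new_points matrix of raw feature rows.
#' @return Embedded coordinates (n x d_iso) with attribute `"fallback"`
#'   marking points outside the training neighborhood radius.
#' @export
transform_oos <- function(model, new_points) {
  z <- scale(as.matrix(new_points), center = model$center, scale = model$scale)
  isomap_transform(model$iso, z)
}

#' @param object a fitted [isosvm()] model.
#' @param newdata matrix of raw feature rows.
#' @param type `"decision"` (default; signed distance, positive toward the
#'   second class level) or `"class"`.
#' @param ... unused.
#' @rdname isosvm
#' @export
predict.isosvm <- function(object, newdata, type = c("decision", "class"), ...) {
  type <- match.arg(type)
  emb <- transform_oos(object, newdata)
  colnames(emb) <- paste0("iso", seq_len(ncol(emb)))
  pr <- stats::predict(object$svm, emb, decision.values = TRUE)
  if (type == "class") return(pr)
  dv <- drop(attr(pr, "decision.values"))
  # libsvm orients decision values toward the first class seen; flip so that
  # positive always means the second factor level
  pos <- object$levels[2L]
  if (!startsWith(colnames(attr(pr, "decision.values"))[1L], pos)) dv <- -dv
  dv
}

#' Leave-one-out cross-validated decision values
#'
#' Each sample is held out once, the Isomap+SVM model refitted on the rest,
#' and the held-out decision value recorded via the out-of-sample transform.
#' Deterministic and independent of sample order. The class receiving the
#' imbalance penalty is fixed once on the full label vector so that every
#' fold trains with the same weighting.
#'
#' @param x,y features and two-level labels.
#' @param k_iso,d_iso,ratio,kernel,cost passed to [isosvm()].
#' @return list with `decision` (length-n LOOCV decision values, positive
#'   toward the second class level), `labels`, `auc`.
#' @export
loocv_isosvm <- function(x, y, k_iso = 60L, d_iso = 10L, ratio = 2,
                         kernel = "radial", cost = 1) {
  x <- as.matrix(x)
  y <- factor(y)
  n <- nrow(x)
  if (n < 10L) stop("need n >= 10 for LOOCV")
  wc <- names(which.min(table(y)))
  dec <- numeric(n)
  for (i in seq_len(n)) {
    m <- isosvm(x[-i, , drop = FALSE], y[-i], k_iso = k_iso, d_iso = d_iso,
                ratio = ratio, kernel = kernel, cost = cost,
                weight_class = wc)
    dec[i] <- predict.isosvm(m, x[i, , drop = FALSE])
  }
  list(decision = dec, labels = y, auc = auc_trapezoid(dec, y))
}

#' Tune the classifier by LOOCV over a hyperparameter grid
#'
#' Every grid point is scored by leave-one-out cross-validated AUC;
#' infeasible points (k_iso >= n - 1 after capping, or k below d_iso + 1)
#' are skipped and logged in the tuning record. The default grid includes
#' the configuration (k_iso = 60, d_iso = 10, ratio = 2).
#'
#' @param x,y features and two-level labels.
#' @param grid data.frame with columns `k_iso`, `d_iso`, `ratio`; default a
#'   small grid around (60, 10, 2).
#' @param kernel,cost passed to [isosvm()].
#' @return list with `best` (the winning row), `record` (the grid with an
#'   `auc` column, NA where skipped), `decision` (the winning grid point's
#'   LOOCV decision values) and `labels`.
#' @export
loocv_tune <- function(x, y,
                       grid = expand.grid(k_iso = c(20L, 40L, 60L),
                                          d_iso = c(5L, 10L),
                                          ratio = c(1, 2)),
                       kernel = "radial", cost = 1) {
  if (nrow(grid) == 0L) stop("empty tuning grid")
  record <- grid
  record$auc <- NA_real_
  runs <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    res <- tryCatch(
      loocv_isosvm(x, y, k_iso = grid$k_iso[g], d_iso = grid$d_iso[g],
                   ratio = grid$ratio[g], kernel = kernel, cost = cost),
      error = function(e) NULL)
    if (!is.null(res)) {
      record$auc[g] <- res$auc
      runs[[g]] <- res
    }
  }
  if (all(is.na(record$auc))) stop("no feasible grid point")
  ibest <- which.max(record$auc)
  list(best = record[ibest, , drop = FALSE], record = record,
       decision = runs[[ibest]]$decision, labels = runs[[ibest]]$labels)
}

# Empirical AUC by the trapezoid rule; identical to the Mann-Whitney
# statistic (ties counted 1/2).
auc_trapezoid <- function(scores, labels) {
  labels <- factor(labels)
  pos <- scores[labels == levels(labels)[2L]]
  neg <- scores[labels == levels(labels)[1L]]
  if (length(pos) == 0L || length(neg) == 0L) stop("both classes required")
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Empirical ROC curve with bootstrap confidence interval
#'
#' The empirical ROC over all score thresholds; AUC by the trapezoid rule
#' (equal to the scaled Mann-Whitney U statistic); percentile confidence
#' interval from a stratified bootstrap (resampling within each class);
#' sensitivity and specificity reported at the Youden-optimal threshold.
#'
#' @param decision_values numeric scores, higher = more positive-class.
#' @param labels two-level factor; second level is the positive class.
#' @param n_boot bootstrap resamples (default 2000).
#' @param conf confidence level (default 0.95).
#' @param seed RNG seed for the bootstrap (default 1).
#' @return An object of class `roc_result`: list with `auc`, `ci`,
#'   `sensitivity`, `specificity`, `threshold`, `curve` (data.frame fpr/tpr),
#'   `decision_values`, `labels`.
#' @export
roc_with_ci <- function(decision_values, labels, n_boot = 2000L,
                        conf = 0.95, seed = 1L) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("need exactly 2 classes")
  pos <- labels == levels(labels)[2L]
  if (!any(pos) || all(pos)) stop("both classes required")
  thr <- c(Inf, sort(unique(decision_values), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(decision_values[pos] >= t), 1)
  fpr <- vapply(thr, function(t) mean(decision_values[!pos] >= t), 1)
  auc <- auc_trapezoid(decision_values, labels)
  youden <- which.max(tpr - fpr)
  boot <- numeric(n_boot)
  old <- .Random.seed_safe()
  set.seed(seed)
  ip <- which(pos); ineg <- which(!pos)
  for (b in seq_len(n_boot)) {
    idx <- c(sample(ip, replace = TRUE), sample(ineg, replace = TRUE))
    boot[b] <- auc_trapezoid(decision_values[idx], labels[idx])
  }
  .Random.seed_restore(old)
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE)
  ci <- c(min(ci[1], auc), max(ci[2], auc))
  structure(list(auc = auc, ci = ci,
                 sensitivity = tpr[youden], specificity = 1 - fpr[youden],
                 threshold = thr[youden],
                 curve = data.frame(fpr = fpr, tpr = tpr, threshold = thr),
                 decision_values = decision_values, labels = labels),
            class = "roc_result")
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (CI %.3f-%.3f), sens = %.1f%%, spec = %.1f%% at Youden threshold %.3g\n",
              x$auc, x$ci[1], x$ci[2], 100 * x$sensitivity,
              100 * x$specificity, x$threshold))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$curve$fpr, x$curve$tpr, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Compare two ROC curves (DeLong test)
#'
#' Two-sided DeLong test for paired or unpaired ROC curves over the stored
#' decision values.
#'
#' @param roc_a,roc_b [roc_with_ci()] results.
#' @param paired whether the curves share the same cases (default: TRUE when
#'   lengths and labels match).
#' @return p-value.
#' @export
roc_compare <- function(roc_a, roc_b, paired = NULL) {
  ra <- pROC::roc(response = roc_a$labels, predictor = roc_a$decision_values,
                  levels = levels(roc_a$labels), direction = "<", quiet = TRUE)
  rb <- pROC::roc(response = roc_b$labels, predictor = roc_b$decision_values,
                  levels = levels(roc_b$labels), direction = "<", quiet = TRUE)
  if (is.null(paired))
    paired <- length(roc_a$labels) == length(roc_b$labels) &&
      all(roc_a$labels == roc_b$labels)
  if (paired && all(roc_a$decision_values == roc_b$decision_values))
    return(1)
  pROC::roc.test(ra, rb, method = "delong", paired = paired)$p.value
}

#' Welch two-sided t-test between two risk groups
#'
#' @param values_a,values_b numeric vectors (each n >= 2). Two groups that
#'   are both constant with equal means leave the statistic undefined (0/0)
#'   and raise an error; both constant with different means gives the
#'   limiting p of 0.
#' @return p-value.
#' @export
group_ttest <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs n >= 2")
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b))
      stop("zero variance in both groups with equal means")
    return(0)
  }
  stats::t.test(values_a, values_b, var.equal = FALSE)$p.value
}
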