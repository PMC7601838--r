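test_that("subspace enumeration matches the binomial closed form", {
  expect_length(enumerate_subspaces(10), 10 + 45 + 120)
  expect_length(enumerate_subspaces(3), 7)
  expect_length(enumerate_subspaces(1), 1)
  for (D in 3:25)
    expect_length(enumerate_subspaces(D),
                  choose(D, 1) + choose(D, 2) + choose(D, 3))
  ss <- enumerate_subspaces(5)
  expect_false(anyDuplicated(vapply(ss, paste, "", collapse = ",")) > 0)
  expect_error(enumerate_subspaces(0), ">= 1")
})

test_that("1-D manifolds embed with perfect rank agreement", {
  x <- matrix(seq(0, 1, length.out = 30), ncol = 1)
  y <- embed_subspace(x, 10)
  expect_equal(abs(cor(y, seq_len(30), method = "spearman")), 1)
  # half circle in 2-D: geodesic order recovered
  t <- seq(0, pi, length.out = 40)
  arc <- cbind(cos(t), sin(t))
  y2 <- embed_subspace(arc, 6)
  expect_equal(abs(cor(y2, seq_len(40), method = "spearman")), 1)
})

test_that("geodesic distances agree with a Floyd-Warshall oracle", {
  set.seed(7)
  X <- matrix(rnorm(20 * 2), 20, 2)
  fit <- radiris:::isomap_fit(X, k = 4, d_out = 1)
  D <- as.matrix(dist(X))
  W <- matrix(Inf, 20, 20)
  for (i in 1:20) {
    nn <- order(D[i, ])[2:5]
    W[i, nn] <- D[i, nn]; W[nn, i] <- D[i, nn]
  }
  fw <- o_floyd(W)
  expect_equal(fit$geo, fw$D, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("the selection gate retains exactly the |R| >= 0.5 embeddings", {
  set.seed(8)
  gt <- rnorm(50)
  # construct embeddings with exact sample correlations 0.6, 0.4, -0.7:
  # unit-variance base aligned with gt plus an orthogonal unit-variance noise
  base <- scale(gt)[, 1]
  noise <- residuals(lm(rnorm(50) ~ base))
  noise <- noise / sd(noise)
  emb <- lapply(c(0.6, 0.4, -0.7), function(r)
    r * base + sqrt(1 - r^2) * noise)
  sel <- score_and_select(emb, gt, threshold = 0.5)
  expect_equal(sel$index, c(1L, 3L))
  expect_equal(sel$R, c(0.6, 0.7), tolerance = 1e-9)
  expect_true(all(apply(sel$U, 2, function(u) cor(u, gt)) > 0))

  # boundary case: R exactly 0.5 is retained
  sel2 <- score_and_select(list(0.5 * base + sqrt(0.75) * noise), gt, 0.5)
  expect_equal(sel2$index, 1L)

  # zero-variance embedding excluded
  sel3 <- score_and_select(list(rep(1, 50), base), gt, 0.5)
  expect_equal(sel3$excluded, 1L)

  # sign invariance of the gate
  sel4 <- score_and_select(lapply(emb, function(e) -e), gt, 0.5)
  expect_equal(sel4$index, sel$index)
  expect_equal(sel4$U, sel$U, tolerance = 1e-9)
})

test_that("feature importance is the retention percentage per parameter", {
  subspaces <- list(1L, c(1L, 2L), c(2L, 3L), 3L)
  es <- list(index = 1:4)
  class(es) <- "embedding_set"
  imp <- feature_importance(es, subspaces, 4, c("A", "B", "C", "D"))
  expect_equal(imp$importance[imp$parameter == "A"], 50)
  expect_equal(imp$importance[imp$parameter == "C"], 50)
  expect_equal(imp$importance[imp$parameter == "D"], 0)
  es2 <- list(index = 1:2); class(es2) <- "embedding_set"
  imp2 <- feature_importance(es2, subspaces, 4, c("A", "B", "C", "D"))
  expect_equal(imp2$importance[imp2$parameter == "A"], 100)
  expect_error(feature_importance(list(index = integer(0)), subspaces, 4),
               "empty")
})

test_that("heatmap clustering identifies redundancy and separated groups", {
  set.seed(10)
  u <- rnorm(30)
  es <- structure(list(U = cbind(u, u, rnorm(30))), class = "embedding_set")
  hm <- cluster_heatmap(es)
  expect_equal(hm$col_hclust$height[1], 0, tolerance = 1e-12)
  expect_true(all(hm$U01 >= 0 & hm$U01 <= 1))

  # three well-separated groups recovered by the 3-cut
  centers <- c(0, 5, 10)
  lab <- rep(1:3, each = 20)
  U <- sapply(1:4, function(j) centers[lab] + rnorm(60, 0, 0.3))
  es2 <- structure(list(U = U), class = "embedding_set")
  hm2 <- cluster_heatmap(es2)
  expect_gte(rand_index(hm2$clusters, lab), 0.9)

  # duplicated patient merges at height zero
  U3 <- rbind(U, U[1, , drop = FALSE])
  es3 <- structure(list(U = U3), class = "embedding_set")
  hm3 <- cluster_heatmap(es3)
  expect_equal(min(hm3$row_hclust$height), 0, tolerance = 1e-12)
  expect_error(cluster_heatmap(structure(list(U = matrix(1, 5, 2)),
                                         class = "embedding_set")),
               "degenerate")
})

test_that("nearest-centroid assignment respects ties and exact hits", {
  hm <- structure(list(U01 = matrix(0, 2, 2),
                       centroids = rbind(c(0, 0), c(1, 1))),
                  class = "heatmap_model")
  expect_equal(assign_patient(hm, c(0, 0)), 1L)
  expect_equal(assign_patient(hm, c(1, 1)), 2L)
  expect_message(tie <- assign_patient(hm, c(0.5, 0.5)), "tie")
  expect_equal(tie, 1L)
  expect_error(assign_patient(hm, c(0, 0, 0)), "mismatch")
})

test_that("the fitted multi-subspace model stratifies synthetic groups", {
  set.seed(12)
  n <- 150
  lab <- sample(rep(1:3, each = n / 3))
  centers <- cbind(c(0, 4, 8), c(0, -4, -8), c(1, 0, -1))
  X <- centers[lab, ] + matrix(rnorm(n * 3, 0, 0.5), n, 3)
  X <- cbind(X, matrix(rnorm(n * 2), n, 2))       # two noise parameters
  colnames(X) <- paste0("P", 1:5)
  risk <- c(10, 24, 40)[lab] + rnorm(n, 0, 2)
  fit <- radiris(X, risk, k_nldr = 10)
  expect_s3_class(fit, "radiris")
  expect_gt(length(fit$selection$index), 0)
  expect_gte(rand_index(fit$heatmap$clusters, lab), 0.9)
  expect_true(all(fit$importance$importance >= 0 &
                    fit$importance$importance <= 100))

  # held-out patients assigned to their generating group's cluster
  m <- 60
  lab_new <- sample(rep(1:3, each = m / 3))
  Xn <- cbind(centers[lab_new, ] + matrix(rnorm(m * 3, 0, 0.5), m, 3),
              matrix(rnorm(m * 2), m, 2))
  pred <- predict(fit, Xn)
  # map generating group -> majority training cluster
  mapping <- vapply(1:3, function(g) {
    as.integer(names(which.max(table(fit$heatmap$clusters[lab == g]))))
  }, integer(1))
  expect_gte(mean(pred == mapping[lab_new]), 0.85)
})

test_that("an unreachable threshold leaves the model empty with a warning", {
  set.seed(14)
  X <- matrix(rnorm(40 * 3), 40, 3)
  risk <- rnorm(40)
  expect_warning(fit <- radiris(X, risk, threshold = 0.999), "threshold")
  expect_null(fit$heatmap)
  expect_error(predict(fit, X), "no heatmap")
})
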