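toy_network <- function(W, names = NULL) {
  # build an informatics_network wrapper around an explicit weight matrix
  if (is.null(names)) names <- LETTERS[seq_len(nrow(W))]
  dimnames(W) <- list(names, names)
  Wg <- ifelse(W > 0, pmax(W, 1e-12), 0)
  g <- igraph::graph_from_adjacency_matrix(Wg, mode = "undirected",
                                           weighted = TRUE)
  structure(list(graph = g, E = W, k = NA, names = names),
            class = "informatics_network")
}

test_that("risk normalization follows the oriented min-max rule", {
  expect_equal(risk_normalize(c(1, 2, 3), r = 0.8), c(0, 0.5, 1))
  expect_equal(risk_normalize(c(1, 2, 3), r = -0.2), c(1, 0.5, 0))
  set.seed(1)
  y <- rnorm(20); gt <- rnorm(20)
  z <- risk_normalize(y, gt)
  expect_equal(min(z), 0); expect_equal(max(z), 1)
  # positive affine invariance
  expect_equal(risk_normalize(3 * y + 7, gt), z, tolerance = 1e-12)
  expect_error(risk_normalize(rep(2, 5), r = 1), "constant")
})

test_that("edge weights are 1 - correlation with k-NN union sparsification", {
  set.seed(2)
  base <- rnorm(30)
  Z <- rbind(a = base, b = base * 2 + 5,        # perfectly correlated
             c = -base,                          # anti-correlated with a
             d = rnorm(30), e = rnorm(30))
  net <- build_network(Z, k = 2)
  expect_equal(net$E["a", "b"], 0, tolerance = 1e-12)
  expect_equal(net$E["a", "c"], 2, tolerance = 1e-12)
  expect_true(isSymmetric(net$E))
  expect_true(all(diag(net$E) == 0))
  expect_error(build_network(Z, k = 5), "smaller")
  expect_error(build_network(rbind(a = rep(1, 5), b = 1:5), k = 1), "constant")
})

test_that("k-NN edge selection matches an exhaustive neighbor sort", {
  set.seed(3)
  for (trial in 1:10) {
    Z <- matrix(rnorm(5 * 40), 5)
    rownames(Z) <- letters[1:5]
    k <- 3
    net <- build_network(Z, k = k)
    E <- net$E
    keep_oracle <- matrix(FALSE, 5, 5)
    for (i in 1:5) {
      w <- E[i, ]; w[i] <- Inf
      nn <- order(w)[1:k]
      keep_oracle[i, nn] <- TRUE
    }
    keep_oracle <- keep_oracle | t(keep_oracle)
    expect_equal(unname(net$keep), keep_oracle)
    expect_true(all(igraph::degree(net$graph) >= k))
  }
})

test_that("path metrics match hand enumeration", {
  tri <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3)
  pm <- path_metrics(toy_network(tri))
  expect_equal(pm$average_path_length, 1)
  expect_equal(pm$diameter, 1)
  # path A-B-C with weights 1 and 2
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 1; W[2, 3] <- W[3, 2] <- 2
  pm2 <- path_metrics(toy_network(W))
  expect_equal(pm2$average_path_length, 2)
  expect_equal(pm2$diameter, 3)
})

test_that("clustering coefficients hit the triangle and star limits", {
  tri <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3)
  expect_equal(clustering_stats(toy_network(tri))$average_clustering, 1)
  star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(clustering_stats(toy_network(star))$average_clustering, 0)
})

test_that("centralities match hand sums on the weighted path graph", {
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 1; W[2, 3] <- W[3, 2] <- 1
  rep_ <- centralities(toy_network(W))
  expect_equal(rep_$betweenness[rep_$parameter == "B"], 1)
  expect_equal(rep_$betweenness[rep_$parameter == "A"], 0)
  expect_equal(rep_$harmonic[rep_$parameter == "B"], 2)
  expect_equal(rep_$harmonic[rep_$parameter == "A"], 1.5)
  # B is maximal in all three metrics -> integrated centrality 1
  expect_equal(rep_$integrated[rep_$parameter == "B"], 1)
})

test_that("hub ranking is centrality-descending with alphabetical ties", {
  rep_ <- data.frame(parameter = c("b", "a", "c"),
                     integrated = c(0.5, 0.5, 0.9))
  expect_message(h <- hub_nodes(rep_, 3), "tie")
  expect_equal(h$parameter, c("c", "a", "b"))
  expect_error(hub_nodes(rep_, 4), "exceeds")
  # a planted high-degree bridge dominates the ranking
  W <- matrix(0, 7, 7)
  W[1, 2] <- W[2, 3] <- W[3, 1] <- 1            # clique-ish side 1
  W[5, 6] <- W[6, 7] <- W[7, 5] <- 1            # side 2
  W[4, c(1, 2, 3, 5, 6, 7)] <- 1                # bridge vertex 4
  W <- pmax(W, t(W))
  net <- toy_network(W)
  h2 <- hub_nodes(centralities(net), 1)
  expect_equal(h2$parameter, "D")
})

test_that("graph metrics equal brute-force oracles on random weighted graphs", {
  set.seed(4)
  for (trial in 1:25) {
    n <- sample(5:10, 1)
    W <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (runif(1) < 0.5) W[i, j] <- W[j, i] <- runif(1, 0.1, 2)
    # ensure connectivity via a random spanning path
    ord <- sample(n)
    for (q in 1:(n - 1)) {
      i <- ord[q]; j <- ord[q + 1]
      if (W[i, j] == 0) W[i, j] <- W[j, i] <- runif(1, 0.1, 2)
    }
    net <- toy_network(W, names = sprintf("V%02d", 1:n))
    Winf <- ifelse(W > 0, W, Inf); diag(Winf) <- 0
    fw <- o_floyd(Winf)
    pm <- path_metrics(net)
    ut <- fw$D[upper.tri(fw$D)]
    expect_equal(pm$average_path_length, mean(ut), tolerance = 1e-9)
    expect_equal(pm$diameter, max(ut), tolerance = 1e-9)
    rep_ <- centralities(net)
    expect_equal(rep_$degree, colSums(W > 0), ignore_attr = TRUE)
    expect_equal(rep_$betweenness, o_betweenness(Winf), tolerance = 1e-8)
    expect_equal(rep_$harmonic, o_harmonic(Winf), tolerance = 1e-9)
    cs <- clustering_stats(net)
    expect_equal(cs$average_clustering, mean(o_clustering(W)), tolerance = 1e-12)
  }
})

test_that("increasing k never removes edges", {
  set.seed(5)
  Z <- matrix(rnorm(8 * 50), 8)
  rownames(Z) <- letters[1:8]
  prev <- NULL
  for (k in 1:6) {
    net <- build_network(Z, k = k)
    edges <- net$keep
    if (!is.null(prev)) expect_true(all(edges[prev]))
    prev <- edges
  }
})
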