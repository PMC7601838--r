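mk_volset <- function(chans) volume_set(chans)

test_that("tissue signatures are length-N vectors per ROI voxel", {
  set.seed(1)
  chans <- setNames(lapply(1:4, function(i) array(rnorm(4 * 4 * 2), c(4, 4, 2))),
                    paste0("c", 1:4))
  m <- array(TRUE, c(4, 4, 2))
  f <- build_signatures(mk_volset(chans), m)
  expect_equal(dim(f$S), c(32L, 4L))
  f1 <- build_signatures(mk_volset(chans[1]), m)
  expect_equal(ncol(f1$S), 1L)
  expect_error(build_signatures(mk_volset(chans), array(TRUE, c(3, 3, 2))),
               "shape")
})

test_that("permuting channel order leaves TSPM features unchanged", {
  set.seed(2)
  chans <- setNames(lapply(1:3, function(i) array(rnorm(5 * 5 * 1), c(5, 5, 1))),
                    c("a", "b", "c"))
  m <- array(TRUE, c(5, 5, 1))
  t1 <- tspm_features(build_signatures(mk_volset(chans), m), B = 4)
  t2 <- tspm_features(build_signatures(mk_volset(chans[c(3, 1, 2)]), m), B = 4)
  expect_equal(t1, t2, tolerance = 1e-12)
})

test_that("TSPM entropy, uniformity and MI hit their analytic limits", {
  m <- array(TRUE, c(4, 4, 1))
  cst <- mk_volset(list(a = array(1, c(4, 4, 1)), b = array(2, c(4, 4, 1))))
  t0 <- tspm_features(build_signatures(cst, m), B = 4)
  expect_equal(unname(t0["entropy"]), 0)
  expect_equal(unname(t0["uniformity"]), 1)
  expect_equal(unname(t0["mutual_information"]), 0)

  # two equiprobable signature cells
  half <- array(rep(c(0, 10), each = 8), c(4, 4, 1))
  t2 <- tspm_features(build_signatures(mk_volset(list(a = half)), m), B = 2)
  expect_equal(unname(t2["entropy"]), 1)
  expect_equal(unname(t2["uniformity"]), 0.5)
})

test_that("independent uniform channels have near-zero mutual information", {
  set.seed(3)
  n <- 40
  chans <- list(a = array(runif(n * n), c(n, n, 1)),
                b = array(runif(n * n), c(n, n, 1)))
  m <- array(TRUE, c(n, n, 1))
  t <- tspm_features(build_signatures(mk_volset(chans), m), B = 4)
  # plug-in MI bias for a B x B joint on n^2 samples is ~(B-1)^2/(2 n^2 ln 2)
  expect_lt(unname(t["mutual_information"]), 0.02)
})

test_that("TSFOS operates on the pooled standardized sample", {
  m <- array(TRUE, c(4, 4, 1))
  cst <- mk_volset(list(a = array(3, c(4, 4, 1)), b = array(9, c(4, 4, 1))))
  f <- tsfos_features(build_signatures(cst, m))
  expect_equal(unname(f["variance"]), 0)
  expect_equal(unname(f["entropy"]), 0)
  # symmetric pooled distribution has zero skewness
  sym <- mk_volset(list(a = array(c(-2, -1, 1, 2), c(4, 4, 1))))
  fs <- tsfos_features(build_signatures(sym, m))
  expect_equal(unname(fs["skewness"]), 0, tolerance = 1e-12)
  # oracle recomputation on a 2-channel ROI
  set.seed(5)
  chans <- list(a = array(rnorm(16, 5, 2), c(4, 4, 1)),
                b = array(rnorm(16, -1, 3), c(4, 4, 1)))
  expect_equal(tsfos_features(build_signatures(mk_volset(chans), m)),
               o_tsfos(chans, m), tolerance = 1e-9)
})

test_that("TSCM limits and spatial sensitivity behave as specified", {
  m <- array(TRUE, c(4, 4, 1))
  cst <- mk_volset(list(a = array(1, c(4, 4, 1)), b = array(5, c(4, 4, 1))))
  t0 <- tscm_features(build_signatures(cst, m), B = 4)
  expect_equal(unname(t0["contrast1"]), 0)
  expect_equal(unname(t0["energy"]), 1)

  # two-phase striped ROI: hand-enumerated 0-degree pairs
  stripes <- array(rep(c(0, 0, 10, 10), times = 4), c(4, 4, 1))
  ts <- tscm_features(build_signatures(mk_volset(list(a = stripes)), m), B = 2)
  expect_equal(ts, o_tscm(list(a = stripes), m, 2), tolerance = 1e-12)

  # shuffling voxel positions changes TSCM but not TSPM
  set.seed(9)
  ch <- array(rnorm(36), c(6, 6, 1))
  m6 <- array(TRUE, c(6, 6, 1))
  perm <- sample(36)
  ch_sh <- array(as.vector(ch)[perm], c(6, 6, 1))
  f1 <- build_signatures(mk_volset(list(a = ch)), m6)
  f2 <- build_signatures(mk_volset(list(a = ch_sh)), m6)
  expect_equal(tspm_features(f1, 4), tspm_features(f2, 4), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(tscm_features(f1, 4), tscm_features(f2, 4),
                                tolerance = 1e-6)))
})

test_that("positive affine channel rescaling leaves mpRad features unchanged", {
  set.seed(11)
  chans <- list(a = array(rnorm(25, 10, 3), c(5, 5, 1)),
                b = array(rnorm(25, 2, 1), c(5, 5, 1)))
  m <- array(TRUE, c(5, 5, 1))
  resc <- list(a = chans$a * 7 + 100, b = chans$b * 0.01 - 5)
  v1 <- mprad_features(mk_volset(chans), m, B = 4)
  v2 <- mprad_features(mk_volset(resc), m, B = 4)
  expect_equal(v1, v2, tolerance = 1e-9)
})

test_that("single-channel TSCM at full occupancy reduces to the GLCM features", {
  # all 8 levels occupied so codeword ranks coincide with gray levels
  set.seed(13)
  vals <- matrix(sample(rep(0:7, 5), 36), 6, 6)
  ch <- array(vals, c(6, 6, 1)) * 1.0
  m <- array(TRUE, c(6, 6, 1))
  ts <- tscm_features(build_signatures(mk_volset(list(a = ch)), m), B = 8)
  g <- glcm_features(quantize(ch, m, 8))
  map <- c(contrast1 = "contrast", autocorrelation1 = "autocorrelation",
           variance1 = "variance", dissimilarity1 = "dissimilarity",
           homogeneity2 = "homogeneity2", idn = "idn", idmn = "idmn",
           sum_variance = "sum_variance", energy = "energy",
           entropy = "entropy")
  for (tn in names(map))
    expect_equal(unname(ts[tn]), unname(g[map[tn]]), tolerance = 1e-9,
                 info = tn)
})

test_that("TSPM probability mass and bounds are respected", {
  set.seed(15)
  for (i in 1:10) {
    r <- random_roi(6, 6)
    chans <- list(a = r$channel, b = array(runif(36), c(6, 6, 1)))
    m <- array(TRUE, c(6, 6, 1))
    f <- build_signatures(mk_volset(chans), m)
    cells <- radiris:::tspm_cells(f, 4)
    expect_equal(sum(cells$p), 1, tolerance = 1e-12)
    t <- tspm_features(f, 4)
    expect_lte(t["entropy"], log2(min(36, 4^2)) + 1e-12)
    expect_gte(t["uniformity"] * length(cells$p), 1 - 1e-12)
  }
})
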