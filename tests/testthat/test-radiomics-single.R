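as_vol <- function(m) array(m, dim = c(nrow(m), ncol(m), 1))
full_mask <- function(m) array(TRUE, dim = c(nrow(m), ncol(m), 1))

test_that("quantization follows the min-max equal-width rule", {
  ch <- as_vol(matrix(0:63, 8, 8))
  q <- quantize(ch, full_mask(ch[, , 1]), 64)
  expect_equal(sort(unique(as.vector(q$levels))), 1:64)
  expect_equal(q$levels[ch == 17], 18L)       # one level per value
  cst <- quantize(as_vol(matrix(5, 4, 4)), array(TRUE, c(4, 4, 1)), 64)
  expect_true(all(cst$levels[cst$mask] == 1L))
  edge <- quantize(array(c(0, 63.999, 0, 0), c(2, 2, 1)),
                   array(TRUE, c(2, 2, 1)), 64)
  expect_equal(sort(unique(edge$levels[edge$mask])), c(1L, 64L))
  expect_error(quantize(ch, array(FALSE, dim = dim(ch)), 64), "empty")
})

test_that("first-order statistics match hand computation on a 3x3 patch", {
  vals <- matrix(c(1, 2, 2, 3, 3, 3, 4, 4, 5), 3, 3)
  q <- quantize(as_vol(vals), full_mask(vals), 4)
  f <- fos_features(q)
  x <- as.vector(vals)
  expect_equal(unname(f["mean"]), mean(x))
  expect_equal(unname(f["median"]), median(x))
  expect_equal(unname(f["variance"]), var(x))
  expect_equal(unname(f["energy"]), sum(x^2))
  expect_equal(unname(f["range"]), 4)
  expect_equal(unname(f["mad"]), mean(abs(x - mean(x))))
  expect_equal(unname(f["rms"]), sqrt(mean(x^2)))
  m2 <- mean((x - mean(x))^2)
  expect_equal(unname(f["skewness"]), mean((x - mean(x))^3) / m2^1.5)
  expect_equal(unname(f["kurtosis"]), mean((x - mean(x))^4) / m2^2)
})

test_that("histogram entropy and uniformity hit their analytic limits", {
  ch <- as_vol(matrix(0:63, 8, 8))
  f <- fos_features(quantize(ch, full_mask(ch[, , 1]), 64))
  expect_equal(unname(f["entropy"]), 6)           # log2(64) bits
  expect_equal(unname(f["uniformity"]), 1 / 64)
  cst <- fos_features(quantize(as_vol(matrix(2, 4, 4)),
                               array(TRUE, c(4, 4, 1)), 64))
  expect_equal(unname(cst["entropy"]), 0)
  expect_equal(unname(cst["uniformity"]), 1)
})

test_that("GLCM limits and hand-enumerated cases are exact", {
  cst <- quantize(as_vol(matrix(3, 4, 4)), array(TRUE, c(4, 4, 1)), 64)
  g <- glcm_features(cst)
  expect_equal(unname(g["energy"]), 1)
  expect_equal(unname(g["entropy"]), 0)
  expect_equal(unname(g["contrast"]), 0)
  expect_equal(unname(g["max_probability"]), 1)

  # 2x2 image [[1,1],[2,2]] (rows), 0-degree pairs: (1,1) and (2,2)
  img <- array(c(1, 2, 1, 2), c(2, 2, 1)) * 1.0
  q <- quantize(img, array(TRUE, c(2, 2, 1)), 2)
  P0 <- radiris:::glcm_probs(q$levels, q$mask, 2)[["0"]]
  expect_equal(P0, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  s <- radiris:::glcm_stats(P0, 2)
  expect_equal(unname(s["energy"]), 0.5)
  expect_equal(unname(s["entropy"]), 1)

  # checkerboard: every 0-degree pair differs by one level
  cb <- array(as.numeric((outer(1:4, 1:4, "+")) %% 2), c(4, 4, 1))
  qc <- quantize(cb, array(TRUE, c(4, 4, 1)), 2)
  Pc <- radiris:::glcm_probs(qc$levels, qc$mask, 2)[["0"]]
  expect_equal(unname(radiris:::glcm_stats(Pc, 2)["contrast"]), 1)
})

test_that("GLRLM run enumeration matches the stated examples", {
  row4 <- array(c(2, 2, 2, 2), c(1, 4, 1))
  q <- quantize(row4 + 0.0, array(TRUE, c(1, 4, 1)), 4)
  runs0 <- radiris:::runs_in_slice(matrix(q$levels[, , 1], 1, 4), "0")
  expect_equal(nrow(runs0), 1L)
  expect_equal(runs0[1, "len"], c(len = 4))
  st <- radiris:::glrlm_stats(runs0, 4)
  expect_equal(unname(st["rp"]), 0.25)

  alt <- array(c(1, 2, 1, 2), c(1, 4, 1)) * 1.0
  qa <- quantize(alt, array(TRUE, c(1, 4, 1)), 2)
  runsA <- radiris:::runs_in_slice(matrix(qa$levels[, , 1], 1, 4), "0")
  expect_equal(nrow(runsA), 4L)
  stA <- radiris:::glrlm_stats(runsA, 4)
  expect_equal(unname(stA["sre"]), 1)
  expect_equal(unname(stA["rp"]), 1)
})

test_that("constant images maximize the long-run emphasis", {
  set.seed(4)
  cst <- quantize(array(1, c(5, 5, 1)), array(TRUE, c(5, 5, 1)), 8)
  lre_const <- glrlm_features(cst)["lre"]
  for (i in 1:5) {
    r <- random_roi(5, 5, G = 8)
    q <- quantize(r$channel, r$mask | TRUE, 8)
    expect_lte(glrlm_features(q)["lre"], lre_const + 1e-12)
  }
})

test_that("NGTDM limits and sign properties hold", {
  cst <- quantize(array(1, c(5, 5, 1)), array(TRUE, c(5, 5, 1)), 8)
  f <- ngtdm_features(cst)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["busyness"]), 0)
  spot <- array(1, c(5, 5, 1)); spot[3, 3, 1] <- 10
  fs <- ngtdm_features(quantize(spot, array(TRUE, c(5, 5, 1)), 8))
  expect_gt(unname(fs["contrast"]), 0)
  expect_error(ngtdm_features(quantize(array(1:4, c(2, 2, 1)) * 1.0,
                                       array(TRUE, c(2, 2, 1)), 4)),
               "neighborhood")
})

test_that("direction-averaged texture features are 90-degree rotation invariant", {
  set.seed(21)
  for (i in 1:10) {
    r <- random_roi(6, 6, G = 8)
    m <- array(TRUE, c(6, 6, 1))
    rot <- array(t(apply(r$channel[, , 1], 2, rev)), c(6, 6, 1))
    q1 <- quantize(r$channel, m, 8)
    q2 <- quantize(rot, m, 8)
    expect_equal(glcm_features(q1), glcm_features(q2), tolerance = 1e-9)
    expect_equal(glrlm_features(q1), glrlm_features(q2), tolerance = 1e-9)
  }
})

test_that("fractal and convexity shape features behave on analytic shapes", {
  n <- 32
  disc <- array(FALSE, c(n, n, 1))
  for (i in 1:n) for (j in 1:n)
    if ((i - 16.5)^2 + (j - 16.5)^2 <= 12^2) disc[i, j, 1] <- TRUE
  set.seed(6)
  fd <- fractal_features(array(runif(n * n), c(n, n, 1)), disc)
  expect_lt(abs(fd["boundary_fd"] - 1.0), 0.1)
  expect_equal(convexity(disc), 1.0, tolerance = 1e-9)

  plus <- array(FALSE, c(9, 9, 1))
  plus[4:6, 2:8, 1] <- TRUE; plus[2:8, 4:6, 1] <- TRUE
  expect_lt(convexity(plus), 1)
  expect_error(convexity(array(c(TRUE, rep(FALSE, 7)), c(2, 2, 2))),
               "degenerate")
})

test_that("feature maps hit their analytic limits", {
  m <- array(TRUE, c(7, 7, 1))
  cst <- array(5, c(7, 7, 1))
  rf <- rfm_maps(cst, m, features = c("fos_entropy", "fos_uniformity"),
                 window = 3)
  expect_true(all(rf$maps$fos_entropy[m] == 0))
  expect_true(all(rf$maps$fos_uniformity[m] == 1))
  ramp <- array(rep(1:7, times = 7), c(7, 7, 1)) * 1.0
  rl <- rfm_maps(ramp, m, features = "laplacian")
  interior <- rl$maps$laplacian[2:6, 2:6, 1]
  expect_true(all(abs(interior) < 1e-10))
  expect_error(rfm_maps(cst, m, features = "fos_entropy", window = 4),
               "odd")
  expect_error(rfm_maps(cst, m, features = "fos_entropy", window = 9),
               "extent")
})

test_that("windowed GLCM entropy maps match a brute-force sliding window", {
  set.seed(31)
  r <- random_roi(7, 7, G = 8)
  m <- array(TRUE, c(7, 7, 1))
  rf <- rfm_maps(r$channel, m, features = "glcm_entropy", window = 3, G = 8)
  q <- quantize(r$channel, m, 8)
  for (i in c(2, 4, 6)) for (j in c(2, 4, 6)) {
    lv <- q$levels[(i - 1):(i + 1), (j - 1):(j + 1), 1, drop = FALSE]
    mk <- array(TRUE, dim(lv))
    expect_equal(rf$maps$glcm_entropy[i, j, 1],
                 unname(o_glcm(lv, mk, 8)["entropy"]), tolerance = 1e-9)
  }
})

test_that("the assembled single-parameter vector has 51 finite features", {
  set.seed(41)
  ch <- array(runif(10 * 10 * 3), c(10, 10, 3))
  m <- array(FALSE, c(10, 10, 3)); m[3:8, 3:8, 1:3] <- TRUE
  v <- radiomic_vector(ch, m, G = 16)
  expect_length(v, 51L)
  expect_true(all(is.finite(v)))
  expect_equal(sum(startsWith(names(v), "FOS_")), 14L)
  expect_equal(sum(startsWith(names(v), "GLCM_")), 18L)
  expect_equal(sum(startsWith(names(v), "GLRLM_")), 11L)
  expect_equal(sum(startsWith(names(v), "NGTDM_")), 5L)
})
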