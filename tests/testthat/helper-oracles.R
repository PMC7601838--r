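# Brute-force reference implementations used as independent oracles.
# Everything here is written with explicit loops over voxels, level pairs
# and graph vertices, deliberately avoiding the vectorized code paths of the
# package.

o_dirs <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L),
               `135` = c(-1L, -1L))

o_quantize <- function(vals, G) {
  lo <- min(vals); hi <- max(vals)
  if (hi <= lo) return(rep(1L, length(vals)))
  q <- integer(length(vals))
  for (i in seq_along(vals)) {
    q[i] <- floor((vals[i] - lo) / (hi - lo) * G) + 1L
    if (q[i] > G) q[i] <- G
  }
  q
}

o_fos <- function(vals, levels, G) {
  n <- length(vals)
  mu <- sum(vals) / n
  m2 <- sum((vals - mu)^2) / n
  m3 <- sum((vals - mu)^3) / n
  m4 <- sum((vals - mu)^4) / n
  srt <- sort(vals)
  med <- if (n %% 2 == 1) srt[(n + 1) / 2] else (srt[n / 2] + srt[n / 2 + 1]) / 2
  p <- numeric(G)
  for (i in seq_len(n)) p[levels[i]] <- p[levels[i]] + 1 / n
  ent <- 0; uni <- 0
  for (g in seq_len(G)) {
    if (p[g] > 0) ent <- ent - p[g] * log2(p[g])
    uni <- uni + p[g]^2
  }
  c(mean = mu, median = med,
    sd = if (n > 1) sqrt(sum((vals - mu)^2) / (n - 1)) else 0,
    variance = if (n > 1) sum((vals - mu)^2) / (n - 1) else 0,
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    energy = sum(vals^2), entropy = ent, uniformity = uni,
    min = min(vals), max = max(vals), range = max(vals) - min(vals),
    mad = sum(abs(vals - mu)) / n, rms = sqrt(sum(vals^2) / n))
}

# Symmetric GLCM pair counts of one slice for one offset, by voxel loops.
o_glcm_counts <- function(lv, msk, off, G) {
  M <- matrix(0, G, G)
  nr <- nrow(lv); nc <- ncol(lv)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    i2 <- i + off[1]; j2 <- j + off[2]
    if (i2 >= 1 && i2 <= nr && j2 >= 1 && j2 <= nc &&
        msk[i, j] && msk[i2, j2]) {
      a <- lv[i, j]; b <- lv[i2, j2]
      M[a, b] <- M[a, b] + 1
      M[b, a] <- M[b, a] + 1
    }
  }
  M
}

o_glcm_stats <- function(P, G) {
  L <- nrow(P)
  px <- numeric(L)
  for (i in 1:L) for (j in 1:L) px[i] <- px[i] + P[i, j]
  mu <- 0; for (i in 1:L) mu <- mu + i * px[i]
  sg2 <- 0; for (i in 1:L) sg2 <- sg2 + (i - mu)^2 * px[i]
  ac <- ct <- cs <- cp <- ds <- en <- et <- h1 <- h2 <- vr <- idn <- idmn <- 0
  mp <- 0
  psum <- numeric(2 * L); pdiff <- numeric(L)
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    ac <- ac + i * j * p
    ct <- ct + (i - j)^2 * p
    cs <- cs + (i + j - 2 * mu)^3 * p
    cp <- cp + (i + j - 2 * mu)^4 * p
    ds <- ds + abs(i - j) * p
    en <- en + p^2
    if (p > 0) et <- et - p * log2(p)
    h1 <- h1 + p / (1 + abs(i - j))
    h2 <- h2 + p / (1 + (i - j)^2)
    vr <- vr + (i - mu)^2 * p
    idn <- idn + p / (1 + abs(i - j) / G)
    idmn <- idmn + p / (1 + (i - j)^2 / G^2)
    if (p > mp) mp <- p
    psum[i + j] <- psum[i + j] + p
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p
  }
  sa <- 0; for (k in 2:(2 * L)) sa <- sa + k * psum[k]
  sv <- 0; se <- 0
  for (k in 2:(2 * L)) {
    sv <- sv + (k - sa)^2 * psum[k]
    if (psum[k] > 0) se <- se - psum[k] * log2(psum[k])
  }
  de <- 0
  for (k in 1:L) if (pdiff[k] > 0) de <- de - pdiff[k] * log2(pdiff[k])
  cr <- if (sg2 > .Machine$double.eps) (ac - mu^2) / sg2 else 1
  c(autocorrelation = ac, contrast = ct, correlation = cr,
    cluster_shade = cs, cluster_prominence = cp, dissimilarity = ds,
    energy = en, entropy = et, homogeneity1 = h1, homogeneity2 = h2,
    max_probability = mp, variance = vr, sum_average = sa,
    sum_variance = sv, sum_entropy = se, difference_entropy = de,
    idn = idn, idmn = idmn)
}

o_glcm <- function(lv3, msk3, G) {
  acc <- NULL; ndir <- 0
  for (off in o_dirs) {
    tot <- matrix(0, G, G)
    for (k in seq_len(dim(lv3)[3])) {
      lv <- lv3[, , k]; lv[is.na(lv)] <- 0L
      tot <- tot + o_glcm_counts(lv, msk3[, , k], off, G)
    }
    if (sum(tot) == 0) next
    tot <- tot / sum(tot)
    acc <- if (is.null(acc)) o_glcm_stats(tot, G) else acc + o_glcm_stats(tot, G)
    ndir <- ndir + 1
  }
  acc / ndir
}

o_glrlm <- function(lv3, msk3, n_vox) {
  per_dir <- list()
  for (dn in names(o_dirs)) {
    off <- o_dirs[[dn]]
    runs <- matrix(numeric(0), ncol = 2)
    for (k in seq_len(dim(lv3)[3])) {
      lv <- lv3[, , k]; msk <- msk3[, , k]
      nr <- nrow(lv); nc <- ncol(lv)
      started <- matrix(FALSE, nr, nc)
      for (i in seq_len(nr)) for (j in seq_len(nc)) {
        if (!msk[i, j] || started[i, j]) next
        # only start a run if the previous cell along the direction is not a
        # continuation of the same run
        pi_ <- i - off[1]; pj <- j - off[2]
        if (pi_ >= 1 && pi_ <= nr && pj >= 1 && pj <= nc &&
            msk[pi_, pj] && lv[pi_, pj] == lv[i, j]) next
        len <- 0L; ci <- i; cj <- j
        while (ci >= 1 && ci <= nr && cj >= 1 && cj <= nc &&
               msk[ci, cj] && lv[ci, cj] == lv[i, j]) {
          started[ci, cj] <- TRUE
          len <- len + 1L
          ci <- ci + off[1]; cj <- cj + off[2]
        }
        runs <- rbind(runs, c(lv[i, j], len))
      }
    }
    nrn <- nrow(runs)
    iL <- runs[, 1]; rL <- runs[, 2]
    gln <- 0
    for (g in unique(iL)) gln <- gln + sum(iL == g)^2
    rln <- 0
    for (r in unique(rL)) rln <- rln + sum(rL == r)^2
    per_dir[[dn]] <- c(sre = sum(1 / rL^2) / nrn, lre = sum(rL^2) / nrn,
                       gln = gln / nrn, rln = rln / nrn, rp = nrn / n_vox,
                       lgre = sum(1 / iL^2) / nrn, hgre = sum(iL^2) / nrn,
                       srlge = sum(1 / (iL^2 * rL^2)) / nrn,
                       srhge = sum(iL^2 / rL^2) / nrn,
                       lrlge = sum(rL^2 / iL^2) / nrn,
                       lrhge = sum(iL^2 * rL^2) / nrn)
  }
  Reduce(`+`, per_dir) / length(per_dir)
}

o_ngtdm <- function(lv3, msk3, G) {
  s <- numeric(G); n <- numeric(G)
  d <- dim(lv3)
  for (k in seq_len(d[3])) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (!msk3[i, j, k]) next
    nb <- c()
    ok <- TRUE
    for (a in -1:1) for (b in -1:1) {
      if (a == 0 && b == 0) next
      i2 <- i + a; j2 <- j + b
      if (i2 < 1 || i2 > d[1] || j2 < 1 || j2 > d[2] || !msk3[i2, j2, k]) {
        ok <- FALSE
      } else nb <- c(nb, lv3[i2, j2, k])
    }
    if (!ok) next
    g <- lv3[i, j, k]
    s[g] <- s[g] + abs(g - mean(nb))
    n[g] <- n[g] + 1
  }
  N <- sum(n)
  p <- n / N
  pres <- which(n > 0)
  Ng <- length(pres)
  psum <- sum(p * s)
  ct <- 0
  if (Ng > 1) {
    for (i in pres) for (j in pres) ct <- ct + p[i] * p[j] * (i - j)^2
    ct <- ct / (Ng * (Ng - 1)) * sum(s) / N
  }
  bden <- 0
  for (i in pres) for (j in pres) bden <- bden + abs(i * p[i] - j * p[j])
  cx <- 0
  for (i in pres) for (j in pres)
    cx <- cx + abs(i - j) * (p[i] * s[i] + p[j] * s[j]) / (N * (p[i] + p[j]))
  st <- 0
  for (i in pres) for (j in pres) st <- st + (p[i] + p[j]) * (i - j)^2
  c(coarseness = if (psum > 0) 1 / psum else Inf,
    contrast = ct,
    busyness = if (bden > 0) psum / bden else 0,
    complexity = cx,
    strength = if (sum(s) > 0) st / sum(s) else 0)
}

# Gift-wrapping convex hull + winding rasterisation, independent of chull().
o_convexity <- function(msk3) {
  d <- dim(msk3)
  n_roi <- 0; n_hull <- 0
  for (k in seq_len(d[3])) {
    pts <- which(msk3[, , k], arr.ind = TRUE)
    if (nrow(pts) == 0) next
    n_roi <- n_roi + nrow(pts)
    if (nrow(pts) <= 2) { n_hull <- n_hull + nrow(pts); next }
    # gift wrapping (Jarvis march): at each step pick the candidate such
    # that every other point lies on its non-clockwise side
    start <- which.min(pts[, 1] * 1e6 + pts[, 2])
    hull <- start
    repeat {
      cur <- hull[length(hull)]
      cand <- NULL
      for (q in seq_len(nrow(pts))) {
        if (q == cur) next
        if (is.null(cand)) { cand <- q; next }
        cr <- (pts[cand, 1] - pts[cur, 1]) * (pts[q, 2] - pts[cur, 2]) -
          (pts[cand, 2] - pts[cur, 2]) * (pts[q, 1] - pts[cur, 1])
        d_cand <- sum((pts[cand, ] - pts[cur, ])^2)
        d_q <- sum((pts[q, ] - pts[cur, ])^2)
        if (cr < -1e-12 || (abs(cr) <= 1e-12 && d_q > d_cand)) cand <- q
      }
      if (cand == start) break
      hull <- c(hull, cand)
      if (length(hull) > nrow(pts)) break
    }
    vx <- pts[hull, 1]; vy <- pts[hull, 2]
    # normalize to counter-clockwise orientation (shoelace)
    if (length(vx) >= 3) {
      area2 <- sum(vx * c(vy[-1], vy[1]) - c(vx[-1], vx[1]) * vy)
      if (area2 < 0) { vx <- rev(vx); vy <- rev(vy) }
    }
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      nv <- length(vx)
      if (nv < 3) next
      inside <- TRUE
      for (e in seq_len(nv)) {
        e2 <- if (e == nv) 1 else e + 1
        cr <- (vx[e2] - vx[e]) * (j - vy[e]) - (vy[e2] - vy[e]) * (i - vx[e])
        if (cr < -1e-9) { inside <- FALSE; break }
      }
      if (inside && i >= min(vx) && i <= max(vx) && j >= min(vy) && j <= max(vy))
        n_hull <- n_hull + 1
    }
    if (length(hull) < 3) n_hull <- n_hull + nrow(pts)
  }
  min(1, n_roi / n_hull)
}

# --- multiparametric oracles -------------------------------------------------

o_standardize <- function(v) {
  s <- sqrt(sum((v - mean(v))^2) / (length(v) - 1))
  if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
}

o_bin <- function(v, B) {
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(rep(1L, length(v)))
  q <- floor((v - lo) / (hi - lo) * B) + 1L
  ifelse(q > B, B, q)
}

o_tspm <- function(vols, msk3, B) {
  S <- sapply(vols, function(ch) o_standardize(ch[msk3]))
  if (is.null(dim(S))) S <- matrix(S, ncol = length(vols))
  bins <- apply(S, 2, o_bin, B = B)
  if (is.null(dim(bins))) bins <- matrix(bins, ncol = length(vols))
  keys <- apply(bins, 1, paste, collapse = "|")
  tab <- table(keys)
  p <- as.numeric(tab) / length(keys)
  ent <- -sum(p * log2(p)); uni <- sum(p^2)
  N <- ncol(bins)
  mi <- 0
  if (N >= 2) {
    cnt <- 0
    for (a in 1:(N - 1)) for (b in (a + 1):N) {
      jt <- matrix(0, B, B)
      for (r in seq_len(nrow(bins))) jt[bins[r, a], bins[r, b]] <-
          jt[bins[r, a], bins[r, b]] + 1
      jt <- jt / sum(jt)
      pa <- rowSums(jt); pb <- colSums(jt)
      m <- 0
      for (i in 1:B) for (j in 1:B)
        if (jt[i, j] > 0) m <- m + jt[i, j] * log2(jt[i, j] / (pa[i] * pb[j]))
      mi <- mi + m; cnt <- cnt + 1
    }
    mi <- mi / cnt
  }
  c(entropy = ent, uniformity = uni, mutual_information = mi)
}

o_tsfos <- function(vols, msk3, G = 64L) {
  S <- sapply(vols, function(ch) o_standardize(ch[msk3]))
  pooled <- as.vector(S)
  o_fos(pooled, o_quantize(pooled, G), G)
}

o_tscm <- function(vols, msk3, B) {
  S <- sapply(vols, function(ch) o_standardize(ch[msk3]))
  if (is.null(dim(S))) S <- matrix(S, ncol = length(vols))
  bins <- apply(S, 2, o_bin, B = B)
  if (is.null(dim(bins))) bins <- matrix(bins, ncol = length(vols))
  keys <- apply(bins, 1, paste, collapse = ",")
  uk <- sort(unique(keys))
  tup <- do.call(rbind, lapply(strsplit(uk, ","), as.integer))
  ord <- do.call(order, c(list(rowMeans(tup)),
                          lapply(seq_len(ncol(tup)), function(j) tup[, j])))
  rk <- integer(length(uk)); rk[ord] <- seq_along(ord)
  code3 <- array(NA_integer_, dim = dim(msk3))
  code3[msk3] <- rk[match(keys, uk)]
  L <- length(uk)
  per_dir <- list()
  for (dn in names(o_dirs)) {
    off <- o_dirs[[dn]]
    M <- matrix(0, L, L)
    d <- dim(msk3)
    for (k in seq_len(d[3])) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      i2 <- i + off[1]; j2 <- j + off[2]
      if (i2 < 1 || i2 > d[1] || j2 < 1 || j2 > d[2]) next
      if (msk3[i, j, k] && msk3[i2, j2, k]) {
        a <- code3[i, j, k]; b <- code3[i2, j2, k]
        M[a, b] <- M[a, b] + 1; M[b, a] <- M[b, a] + 1
      }
    }
    if (sum(M) == 0) next
    P <- M / sum(M)
    g <- o_glcm_stats(P, L)
    iv <- 0
    for (i in 1:L) for (j in 1:L)
      if (i != j) iv <- iv + P[i, j] / (i - j)^2
    per_dir[[dn]] <- c(contrast1 = unname(g["contrast"]),
                       autocorrelation1 = unname(g["autocorrelation"]),
                       variance1 = unname(g["variance"]),
                       dissimilarity1 = unname(g["dissimilarity"]),
                       homogeneity2 = unname(g["homogeneity2"]),
                       idn = unname(g["idn"]), idmn = unname(g["idmn"]),
                       inverse_variance = iv,
                       sum_variance = unname(g["sum_variance"]),
                       energy = unname(g["energy"]),
                       entropy = unname(g["entropy"]))
  }
  Reduce(`+`, per_dir) / length(per_dir)
}

# --- graph oracles -----------------------------------------------------------

# Floyd-Warshall distances and shortest-path counts from a weight matrix
# (0/Inf = no edge).
o_floyd <- function(W) {
  n <- nrow(W)
  D <- W
  Sg <- ifelse(is.finite(W) & W > 0, 1, 0)
  diag(D) <- 0; diag(Sg) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (i == j || k == i || k == j) next
    alt <- D[i, k] + D[k, j]
    if (alt < D[i, j] - 1e-12) {
      D[i, j] <- alt
      Sg[i, j] <- Sg[i, k] * Sg[k, j]
    } else if (abs(alt - D[i, j]) <= 1e-12 && is.finite(alt)) {
      Sg[i, j] <- Sg[i, j] + Sg[i, k] * Sg[k, j]
    }
  }
  list(D = D, S = Sg)
}

o_betweenness <- function(W) {
  n <- nrow(W)
  fw <- o_floyd(W)
  btw <- numeric(n)
  for (v in 1:n) for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (s == v || t == v || !is.finite(fw$D[s, t])) next
    if (abs(fw$D[s, v] + fw$D[v, t] - fw$D[s, t]) <= 1e-9 && fw$S[s, t] > 0)
      btw[v] <- btw[v] + fw$S[s, v] * fw$S[v, t] / fw$S[s, t]
  }
  btw
}

o_harmonic <- function(W) {
  fw <- o_floyd(W)
  n <- nrow(W)
  h <- numeric(n)
  for (i in 1:n) for (j in 1:n)
    if (i != j && is.finite(fw$D[i, j]) && fw$D[i, j] > 0)
      h[i] <- h[i] + 1 / fw$D[i, j]
  h
}

o_clustering <- function(adj) {
  n <- nrow(adj)
  cc <- numeric(n)
  for (v in 1:n) {
    nb <- which(adj[v, ] > 0)
    k <- length(nb)
    if (k < 2) { cc[v] <- 0; next }
    links <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb))
      if (a < b && adj[nb[a], nb[b]] > 0) links <- links + 1
    cc[v] <- 2 * links / (k * (k - 1))
  }
  cc
}

# --- common fixtures ---------------------------------------------------------

random_roi <- function(nr = 6, nc = 6, G = 8, p_mask = 1, min_vox = 4) {
  repeat {
    ch <- array(stats::runif(nr * nc), dim = c(nr, nc, 1))
    m <- array(stats::runif(nr * nc) <= p_mask, dim = c(nr, nc, 1))
    if (sum(m) >= min_vox) return(list(channel = ch, mask = m, G = G))
  }
}

rand_index <- function(a, b) {
  n <- length(a)
  s <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    s <- s + ((a[i] == a[j]) == (b[i] == b[j]))
  s / (n * (n - 1) / 2)
}
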