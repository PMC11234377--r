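# Independent brute-force oracles. Each re-implements the documented contract
# with naive loops / exhaustive enumeration, sharing no code with the package
# internals it checks.

oracle_max_project <- function(planes) {
  out <- planes[[1]]
  for (i in seq(nrow(out))) for (j in seq(ncol(out))) {
    v <- -Inf
    for (p in planes) v <- max(v, p[i, j])
    out[i, j] <- v
  }
  out
}

# truncated normalised Gaussian kernel, built independently
oracle_gaussian_kernel <- function(size, sigma) {
  half <- (size - 1) / 2
  k <- matrix(0, size, size)
  for (i in 1:size) for (j in 1:size)
    k[i, j] <- exp(-((i - half - 1)^2 + (j - half - 1)^2) / (2 * sigma^2))
  k / sum(k)
}

# direct convolution with replicate padding
oracle_convolve <- function(x, k) {
  h <- (nrow(k) - 1) / 2
  out <- x
  nr <- nrow(x); nc <- ncol(x)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    for (di in -h:h) for (dj in -h:h) {
      ii <- min(max(i + di, 1), nr)
      jj <- min(max(j + dj, 1), nc)
      s <- s + x[ii, jj] * k[di + h + 1, dj + h + 1]
    }
    out[i, j] <- s
  }
  out
}

# exhaustive search over candidate bin-edge thresholds maximising
# between-class variance, restricted to [t_min, t_max]
oracle_ranged_otsu <- function(x, t_min = -Inf, t_max = Inf, n_bins = 256) {
  v <- as.vector(x)
  edges <- seq(min(v), max(v), length.out = n_bins + 1)
  cand <- edges[2:n_bins]
  cand <- cand[cand >= t_min & cand <= t_max]
  best <- -Inf; best_t <- NA
  # histogram-based class means, matching the binned contract
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  cnt <- tabulate(findInterval(v, edges, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = n_bins)
  for (t in cand) {
    lo <- mids <= t & cnt > 0
    hi <- mids > t & cnt > 0
    w0 <- sum(cnt[lo]) / sum(cnt); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) { sb <- 0 } else {
      mu0 <- sum(cnt[lo] * mids[lo]) / sum(cnt[lo])
      mu1 <- sum(cnt[hi] * mids[hi]) / sum(cnt[hi])
      sb <- w0 * w1 * (mu0 - mu1)^2
    }
    if (sb > best + 1e-12) { best <- sb; best_t <- t }
  }
  best_t
}

oracle_intensity <- function(v) {
  n <- length(v)
  sv <- sort(v)
  qt <- function(p) {           # type-7 linear interpolation
    hpos <- (n - 1) * p + 1
    lo <- floor(hpos); hi <- ceiling(hpos)
    sv[lo] + (hpos - lo) * (sv[hi] - sv[lo])
  }
  med <- qt(0.5)
  c(mean = sum(v) / n,
    std = sqrt(sum((v - sum(v) / n)^2) / n),
    min = sv[1], max = sv[n], sum = sum(v),
    median = med,
    mad = {
      d <- sort(abs(v - med)); m <- length(d)
      h <- (m - 1) * 0.5 + 1; lo <- floor(h)
      d[lo] + (h - lo) * (d[min(lo + 1, m)] - d[lo])
    },
    p05 = qt(0.05), p25 = qt(0.25), p75 = qt(0.75), p95 = qt(0.95),
    range = sv[n] - sv[1])
}

# per-pixel LBP with explicit bilinear interpolation and the documented
# tie tolerance; returns the normalised 10-bin histogram for one radius
oracle_lbp_hist <- function(img, r) {
  nr <- nrow(img); nc <- ncol(img)
  labs <- c()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (i <= r || i > nr - r || j <= r || j > nc - r) next
    bits <- integer(8)
    for (k in 0:7) {
      ang <- 2 * pi * k / 8
      py <- i + round(r * sin(ang), 8)
      px <- j + round(r * cos(ang), 8)
      y0 <- floor(py); x0 <- floor(px)
      fy <- py - y0; fx <- px - x0
      at <- function(a, b) if (a >= 1 && a <= nr && b >= 1 && b <= nc)
        img[a, b] else 0   # weight is zero whenever out of range
      nb <- (1 - fy) * ((1 - fx) * at(y0, x0) + fx * at(y0, x0 + 1)) +
        fy * ((1 - fx) * at(y0 + 1, x0) + fx * at(y0 + 1, x0 + 1))
      bits[k + 1] <- as.integer(nb >= img[i, j] - 1e-9 * max(abs(img[i, j]), 1))
    }
    transitions <- sum(bits != c(bits[-1], bits[1]))
    labs <- c(labs, if (transitions <= 2) sum(bits) else 9L)
  }
  h <- sapply(0:9, function(l) sum(labs == l))
  h / sum(h)
}

# naive TAS: explicit neighbour counting per window/variant
oracle_tas <- function(img, maskm) {
  v <- img[maskm]
  mu <- mean(v); sg <- sqrt(mean((v - mu)^2))
  nr <- nrow(img); nc <- ncol(img)
  wins <- list(function(x) x >= mu,
               function(x) x >= mu - sg & x <= mu + sg,
               function(x) x >= mu + sg)
  out <- c()
  for (wf in wins) for (variant in 1:2) {
    white <- matrix(FALSE, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc))
      if (maskm[i, j])
        white[i, j] <- if (variant == 1) wf(img[i, j]) else !wf(img[i, j])
    counts <- c()
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (!white[i, j]) next
      s <- 0
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && white[ii, jj])
          s <- s + 1
      }
      counts <- c(counts, s)
    }
    h <- if (length(counts)) sapply(0:8, function(k) sum(counts == k)) /
      length(counts) else rep(0, 9)
    out <- c(out, h)
  }
  out
}

# Hu invariants from raw moment sums
oracle_hu <- function(img, maskm) {
  idx <- which(maskm, arr.ind = TRUE)
  w <- img[maskm]
  m00 <- sum(w)
  xb <- sum(w * idx[, 2]) / m00
  yb <- sum(w * idx[, 1]) / m00
  mu <- function(p, q) sum(w * (idx[, 2] - xb)^p * (idx[, 1] - yb)^q)
  et <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  e20 <- et(2, 0); e02 <- et(0, 2); e11 <- et(1, 1)
  e30 <- et(3, 0); e03 <- et(0, 3); e21 <- et(2, 1); e12 <- et(1, 2)
  h <- numeric(7)
  h[1] <- e20 + e02
  h[2] <- (e20 - e02)^2 + 4 * e11^2
  h[3] <- (e30 - 3 * e12)^2 + (3 * e21 - e03)^2
  h[4] <- (e30 + e12)^2 + (e21 + e03)^2
  h[5] <- (e30 - 3 * e12) * (e30 + e12) * ((e30 + e12)^2 - 3 * (e21 + e03)^2) +
    (3 * e21 - e03) * (e21 + e03) * (3 * (e30 + e12)^2 - (e21 + e03)^2)
  h[6] <- (e20 - e02) * ((e30 + e12)^2 - (e21 + e03)^2) +
    4 * e11 * (e30 + e12) * (e21 + e03)
  h[7] <- (3 * e21 - e03) * (e30 + e12) * ((e30 + e12)^2 - 3 * (e21 + e03)^2) -
    (e30 - 3 * e12) * (e21 + e03) * (3 * (e30 + e12)^2 - (e21 + e03)^2)
  -sign(h) * log10(abs(h) + 1e-30)
}

# Mann-Whitney U and exact two-sided p by full enumeration (no ties)
oracle_mann_whitney <- function(x, y) {
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_stat(x, y)
  pooled <- c(x, y)
  n1 <- length(x)
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
  mu <- length(x) * length(y) / 2
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
  list(U = u_obs, p = min(1, p))
}

# Wilcoxon signed-rank W+ and exact two-sided p over all 2^n sign patterns
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% rk
  mu <- n * (n + 1) / 4
  p <- mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
  list(W = w_obs, p = min(1, p))
}

# Kruskal-Wallis H with tie correction, from first principles
oracle_kruskal <- function(values, groups) {
  rk <- rank(values)
  N <- length(values)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(rk, groups, function(r) length(r) * (mean(r) - (N + 1) / 2)^2))
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}
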