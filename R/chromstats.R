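# Ratio dynamics, positive-fraction scoring and the group-comparison tests
# used throughout the analysis (Mann-Whitney, Kruskal-Wallis + Dunn +
# Bonferroni, Wilcoxon signed-rank, Pearson).

#' Background level per field
#'
#' Median intensity of non-object pixels, per channel; used as the default
#' background subtracted before ratio computation.
#'
#' @param field a `field_image`.
#' @param mask a `label_mask` for the same field.
#' @return named numeric vector, one value per channel.
#' @export
estimate_background <- function(field, mask) {
  bg <- mask$labels == 0
  vapply(field$channels, function(m) stats::median(m[bg]), numeric(1))
}

#' Per-nucleus channel intensity ratio
#'
#' ratio = (GFP_mean - GFP_bg) / (RFP_mean - RFP_bg). Nuclei whose
#' background-subtracted denominator is not positive are flagged missing
#' (`NA`) rather than erroring.
#'
#' @param table a `NucleusFeatureTable`.
#' @param numerator,denominator column names of the channel means.
#' @param background either `NULL` (no subtraction), a length-2 numeric
#'   `c(num, den)` applied to all rows, or a data frame keyed by
#'   (experiment, condition, well, roi, day) with columns `bg_num`, `bg_den`.
#' @return `table` with an added `ratio` column.
#' @export
channel_ratio <- function(table,
                          numerator = "Intensity_GFP_mean",
                          denominator = "Intensity_RFP_mean",
                          background = NULL) {
  num <- table[[numerator]]
  den <- table[[denominator]]
  if (is.null(background)) {
    bg_n <- 0; bg_d <- 0
  } else if (is.numeric(background)) {
    bg_n <- background[1]; bg_d <- background[2]
  } else {
    keys <- c("experiment", "condition", "well", "roi", "day")
    i <- match(interaction(table[keys], drop = FALSE),
               interaction(background[keys], drop = FALSE))
    bg_n <- background$bg_num[i]; bg_d <- background$bg_den[i]
  }
  d <- den - bg_d
  r <- ifelse(d > 0, (num - bg_n) / d, NA_real_)
  table$ratio <- r
  table
}

#' Fraction of nuclei with detectable signal
#'
#' @param table a `NucleusFeatureTable`.
#' @param channel_col intensity column to score.
#' @param threshold detection threshold (signal strictly above counts as
#'   positive).
#' @return list with `percent` and `n`.
#' @export
positive_fraction <- function(table, channel_col, threshold) {
  if (!nrow(table)) stop("empty table")
  if (threshold < 0) stop("threshold must be >= 0")
  v <- table[[channel_col]]
  list(percent = 100 * mean(v > threshold), n = length(v))
}

#' Nonparametric group comparisons
#'
#' Dispatches to the test matching the design: `two_independent` runs a
#' two-sided Mann-Whitney U test; `k_independent` runs Kruskal-Wallis
#' followed by Dunn's pairwise z-tests with Bonferroni correction over all
#' k(k-1)/2 pairs; `paired` runs the Wilcoxon signed-rank test (zero
#' differences dropped). Rank-test p-values are exact for small tie-free
#' samples, exact conditional permutation values for small samples with
#' ties, and normal approximations with tie/continuity correction
#' otherwise.
#'
#' @param values numeric vector of observations.
#' @param groups group labels parallel to `values` (for `paired`, exactly two
#'   groups with matched ordering).
#' @param design one of `two_independent`, `k_independent`, `paired`.
#' @return a `group_comparison` object: list with `test`, `groups`, `n`,
#'   `statistic`, `p_value` and, for the k-sample design, a `pairwise` data
#'   frame with raw and Bonferroni-adjusted p-values.
#' @export
compare_groups <- function(values, groups,
                           design = c("two_independent", "k_independent",
                                      "paired")) {
  design <- match.arg(design)
  groups <- factor(groups)
  split_v <- split(values, groups)
  ns <- vapply(split_v, length, integer(1))
  if (length(split_v) < 2) stop("need at least 2 groups")
  if (any(ns < 3)) stop("insufficient n: need at least 3 per group")

  if (design == "two_independent") {
    if (length(split_v) != 2) stop("two_independent requires exactly 2 groups")
    mw <- mann_whitney_test(split_v[[1]], split_v[[2]])
    res <- list(test = "Mann-Whitney U", groups = levels(groups), n = ns,
                statistic = mw$statistic, p_value = mw$p_value)
  } else if (design == "paired") {
    if (length(split_v) != 2) stop("paired design requires exactly 2 groups")
    if (ns[1] != ns[2]) stop("paired design requires equal-length vectors")
    sr <- signed_rank_test(split_v[[1]] - split_v[[2]])
    res <- list(test = "Wilcoxon signed-rank", groups = levels(groups),
                n = ns, statistic = sr$statistic, p_value = sr$p_value)
  } else {
    ht <- stats::kruskal.test(split_v)
    res <- list(test = "Kruskal-Wallis + Dunn (Bonferroni)",
                groups = levels(groups), n = ns,
                statistic = unname(ht$statistic), p_value = ht$p.value,
                pairwise = dunn_posthoc(values, groups))
  }
  structure(res, class = "group_comparison")
}

# Mann-Whitney U. Exact p (via wilcox.test) when samples are small and free
# of ties; exact conditional permutation p when ties are present but full
# enumeration stays cheap; otherwise the normal approximation with tie and
# continuity correction.
mann_whitney_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  has_ties <- anyDuplicated(c(x, y)) > 0
  u <- sum(rank(c(x, y))[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (!has_ties && n1 < 50 && n2 < 50) {
    ht <- stats::wilcox.test(x, y, exact = TRUE)
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value))
  }
  if (has_ties && choose(n1 + n2, n1) <= 2e5) {
    pooled <- c(x, y)
    rk <- rank(pooled)
    combs <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(rk[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-12)
    return(list(statistic = u, p_value = min(1, p)))
  }
  ht <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

# Wilcoxon signed-rank on differences (zeros dropped). Exact p via
# wilcox.test when tie-free and small; exact sign-flip enumeration over the
# midranks (count-distribution dynamic programming) when ties are present at
# small n; otherwise the normal approximation.
signed_rank_test <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, p_value = 1))
  rk <- rank(abs(d))
  w <- sum(rk[d > 0])
  has_ties <- anyDuplicated(abs(d)) > 0
  if (!has_ties && n < 50) {
    ht <- stats::wilcox.test(d, exact = TRUE)
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value))
  }
  if (n <= 25) {
    ir <- as.integer(round(2 * rk))           # doubled midranks are integers
    counts <- 1
    for (e in ir) {
      ext <- c(counts, rep(0, e))
      counts <- ext + c(rep(0, e), counts)
    }
    sums <- seq_along(counts) - 1
    mu2 <- sum(ir) / 2
    p <- sum(counts[abs(sums - mu2) >= abs(2 * w - mu2) - 1e-9]) / 2^n
    return(list(statistic = w, p_value = min(1, p)))
  }
  ht <- suppressWarnings(stats::wilcox.test(d, exact = FALSE, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

# Dunn's pairwise z-tests on the pooled ranks, Bonferroni over all pairs
dunn_posthoc <- function(values, groups) {
  rk <- rank(values)
  N <- length(values)
  mean_rk <- tapply(rk, groups, mean)
  ns <- tapply(rk, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(groups)
  k <- length(lv)
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  out <- data.frame(group1 = lv[pairs[1, ]], group2 = lv[pairs[2, ]],
                    z = NA_real_, p = NA_real_, p_adj = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[i1] + 1 / ns[i2]))
    z <- (mean_rk[i1] - mean_rk[i2]) / se
    out$z[j] <- z
    out$p[j] <- 2 * stats::pnorm(-abs(z))
    out$p_adj[j] <- min(1, out$p[j] * m)
  }
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$test, x$statistic,
              x$p_value))
  cat("  n:", paste(sprintf("%s=%d", x$groups, x$n), collapse = ", "), "\n")
  if (!is.null(x$pairwise)) {
    cat("  pairwise (Dunn, Bonferroni-adjusted):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Turn a group comparison into a tidy data frame
#' @param x a `group_comparison`.
#' @export
as.data.frame.group_comparison <- function(x, ...) {
  main <- data.frame(test = x$test, group1 = x$groups[1],
                     group2 = paste(x$groups[-1], collapse = "/"),
                     statistic = x$statistic, p = x$p_value, p_adj = NA_real_,
                     stringsAsFactors = FALSE)
  if (is.null(x$pairwise)) return(main)
  rbind(main, data.frame(test = "Dunn z", group1 = x$pairwise$group1,
                         group2 = x$pairwise$group2, statistic = x$pairwise$z,
                         p = x$pairwise$p, p_adj = x$pairwise$p_adj,
                         stringsAsFactors = FALSE))
}

#' Pearson correlation between two features, per group
#'
#' @param table a `NucleusFeatureTable`.
#' @param feature_x,feature_y feature column names.
#' @param by_group grouping column (e.g. "day"); `NULL` for a single group.
#' @return data frame (group, r, n); `r` is `NA` (flagged in `note`) for
#'   zero-variance input, and missing pairs are dropped pairwise.
#' @export
pearson_feature_corr <- function(table, feature_x, feature_y, by_group = NULL) {
  grp <- if (is.null(by_group)) rep("all", nrow(table)) else table[[by_group]]
  res <- lapply(split(seq_len(nrow(table)), grp), function(i) {
    x <- table[[feature_x]][i]; y <- table[[feature_y]][i]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3)
      return(data.frame(r = NA_real_, n = length(x), note = "n < 3"))
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(r = NA_real_, n = length(x), note = "zero variance"))
    data.frame(r = stats::cor(x, y), n = length(x), note = "")
  })
  out <- do.call(rbind, res)
  out <- cbind(data.frame(group = names(res), stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}
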