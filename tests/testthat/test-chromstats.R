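# Ratio quantification, positive-cell scoring and group-comparison tests.

test_that("channel ratio handles background subtraction and flags bad denominators", {
  tbl <- data.frame(Intensity_GFP_mean = c(30, 10, 5),
                    Intensity_RFP_mean = c(60, 20, 2))
  r <- channel_ratio(tbl)
  expect_equal(r$ratio, c(0.5, 0.5, 2.5))
  r2 <- channel_ratio(tbl, background = c(5, 4))
  expect_equal(r2$ratio[1], 25 / 56)
  # non-positive denominator after subtraction -> flagged missing
  expect_true(is.na(channel_ratio(tbl, background = c(0, 2))$ratio[3]))
})

test_that("noise-free simulation recovers the true per-nucleus ratio exactly", {
  cfg <- sim_config(field_size_px = c(192L, 192L), n_zplanes = 3L,
                    nuclei_per_field_mean = 4, bias_field_amplitude = 0,
                    noise = list(poisson_gain = 0, gaussian_sd = 0),
                    background = 0, ratio_cv = 0,
                    days = c(0L, 5L), ratio_mean = c(1, 0.3),
                    heterogeneity_scale = c(1, 0.5),
                    chromocenter_contrast = c(0.6, 1.4),
                    distractor_rates = c(truncated = 0, merged = 0, debris = 0))
  pars <- sample_population(cfg, 5L, seed = 12L)
  fld <- render_field(pars, cfg, seed = 13L)
  fi <- max_project(fld$stacks, metadata = fx_meta(day = 5L))
  mask <- segment_nuclei(fi, t_range = c(0.02, 0.10))
  ft <- channel_ratio(extract_features(fi, mask,
                                       methods = c("morphology", "intensity")))
  expect_gt(nrow(ft), 0)
  expect_true(all(abs(ft$ratio - 0.3) < 1e-6))
})

test_that("positive fraction scores detectable-signal nuclei", {
  tbl <- data.frame(Intensity_GFP_mean = c(rep(0, 4), runif(16, 0.2, 0.9)))
  pf <- positive_fraction(tbl, "Intensity_GFP_mean", 0.05)
  expect_equal(pf$percent, 80)
  expect_equal(pf$n, 20L)
  expect_equal(positive_fraction(tbl[-(1:4), , drop = FALSE],
                                 "Intensity_GFP_mean", 0)$percent, 100)
  expect_equal(positive_fraction(tbl, "Intensity_GFP_mean", 2)$percent, 0)
  expect_error(positive_fraction(tbl[0, , drop = FALSE],
                                 "Intensity_GFP_mean", 0), "empty")
})

test_that("Mann-Whitney matches exact enumeration at small n", {
  set.seed(23)
  for (i in 1:3) {
    x <- round(rnorm(6), 3); y <- round(rnorm(7) + 0.5, 3)
    got <- compare_groups(c(x, y), rep(c("a", "b"), c(6, 7)), "two_independent")
    orc <- oracle_mann_whitney(x, y)
    expect_equal(got$statistic, orc$U)
    expect_equal(got$p_value, orc$p, tolerance = 1e-10)
  }
  # complete separation at n = 20 per group: U = 0 and the minimal exact p
  got <- compare_groups(c(1:20, 101:120), rep(c("a", "b"), each = 20),
                        "two_independent")
  expect_equal(got$statistic, 0)
  expect_equal(got$p_value, 2 / choose(40, 20))
  # identical groups sit at the null
  same <- compare_groups(rep(1:10, 2), rep(c("a", "b"), each = 10),
                         "two_independent")
  expect_gt(same$p_value, 0.9)
  expect_error(compare_groups(1:4, c("a", "a", "b", "b"), "two_independent"),
               "insufficient n")
})

test_that("signed-rank matches exact enumeration and degenerates gracefully", {
  set.seed(29)
  for (i in 1:3) {
    x <- round(rnorm(8), 3); y <- round(x + rnorm(8, 0.3), 3)
    got <- compare_groups(c(x, y), rep(c("a", "b"), each = 8), "paired")
    orc <- oracle_signed_rank(x - y)
    expect_equal(got$statistic, orc$W)
    expect_equal(got$p_value, orc$p, tolerance = 1e-10)
  }
  same <- compare_groups(rep(1:6, 2), rep(c("a", "b"), each = 6), "paired")
  expect_equal(same$p_value, 1)
  expect_error(compare_groups(c(1:5, 1:4), rep(c("a", "b"), c(5, 4)),
                              "paired"), "equal-length")
})

test_that("Kruskal-Wallis + Dunn matches the first-principles statistic", {
  set.seed(31)
  vals <- c(rnorm(8), rnorm(8, 1), rnorm(8, 2))
  grp <- rep(c("g1", "g2", "g3"), each = 8)
  got <- compare_groups(vals, grp, "k_independent")
  expect_equal(got$statistic, oracle_kruskal(vals, grp), tolerance = 1e-10)
  expect_equal(nrow(got$pairwise), 3L)
  expect_true(all(got$pairwise$p_adj >= got$pairwise$p))
  expect_true(all(got$pairwise$p_adj <= 1))
  # three identical groups: H ~ 0, all Dunn-adjusted p = 1
  same <- compare_groups(rep(1:8, 3), rep(c("g1", "g2", "g3"), each = 8),
                         "k_independent")
  expect_lt(same$statistic, 1e-10)
  expect_true(all(same$pairwise$p_adj == 1))
  tidy <- as.data.frame(got)
  expect_equal(nrow(tidy), 4L)
})

test_that("Pearson correlation per group behaves on analytic inputs", {
  tbl <- data.frame(x = c(1:10, 1:10), y = c(2 * (1:10) + 1, -(1:10)),
                    day = rep(c(0, 5), each = 10))
  r <- pearson_feature_corr(tbl, "x", "y", "day")
  expect_equal(r$r[r$group == "0"], 1)
  expect_equal(r$r[r$group == "5"], -1)
  set.seed(37)
  big <- data.frame(x = rnorm(1000), y = rnorm(1000))
  expect_lt(abs(pearson_feature_corr(big, "x", "y")$r), 0.1)
  flat <- data.frame(x = rep(1, 5), y = rnorm(5))
  expect_true(is.na(pearson_feature_corr(flat, "x", "y")$r))
  expect_match(pearson_feature_corr(flat, "x", "y")$note, "zero variance")
})
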