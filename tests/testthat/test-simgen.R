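# Synthetic time-course generator: population sampling, rendering, manifest.

test_that("config validation rejects bad study designs", {
  expect_error(sim_config(days = c(0, 5, 2)), "strictly increasing")
  expect_error(sim_config(field_size_px = c(32, 512)), ">= 64")
  expect_error(sim_config(heterogeneity_scale = -1), ">= 0")
  expect_error(sim_config(noise = list(poisson_gain = -1, gaussian_sd = 0)),
               "noise")
  expect_error(sample_population(sim_config(), day = 3), "unknown day")
})

test_that("zero dispersion collapses the population onto single parameter values", {
  cfg <- sim_config(heterogeneity_scale = 0, ratio_cv = 0,
                    nuclei_per_field_mean = 15,
                    distractor_rates = c(truncated = 0, merged = 0, debris = 0))
  p0 <- sample_population(cfg, 0L, seed = 7L)
  expect_gt(nrow(p0), 3)
  for (col in c("a", "b", "base_int", "n_chromo", "chromo_contrast"))
    expect_equal(length(unique(p0[[col]])), 1L, label = col)
  # zero-CV ratio schedule: every day-5 nucleus carries exactly 0.3
  p5 <- sample_population(cfg, 5L, seed = 8L)
  expect_true(all(p5$ratio == 0.3))
  expect_true(all(p0$ratio == 1.0))
})

test_that("realised nucleus counts follow the Poisson rate", {
  cfg <- sim_config(nuclei_per_field_mean = 50,
                    distractor_rates = c(truncated = 0, merged = 0, debris = 0))
  counts <- vapply(1:200, function(i)
    sum(sample_population(cfg, 0L, seed = 1000L + i)$class == "good"),
    numeric(1))
  se <- sqrt(50 / 200)
  expect_lt(abs(mean(counts) - 50), 3 * se)
})

test_that("rendering is deterministic and consistent with its ground truth", {
  cfg <- sim_config(nuclei_per_field_mean = 8)
  pars <- sample_population(cfg, 0L, seed = 11L)
  f1 <- render_field(pars, cfg, seed = 21L)
  f2 <- render_field(pars, cfg, seed = 21L)
  expect_identical(f1$stacks, f2$stacks)
  # every non-background mask label has exactly one parameter row
  expect_setequal(unique(as.vector(f1$ground_truth$mask[f1$ground_truth$mask > 0])),
                  pars$id)
})

test_that("noise-free rendering is flat inside the mask and empty outside", {
  cfg <- sim_config(field_size_px = c(128L, 128L), n_zplanes = 4L,
                    nuclei_per_field_mean = 1, bias_field_amplitude = 0,
                    noise = list(poisson_gain = 0, gaussian_sd = 0),
                    background = 0,
                    distractor_rates = c(truncated = 0, merged = 0, debris = 0))
  pars <- data.frame(id = 1L, class = "good", cy = 64, cx = 64, a = 14, b = 11,
                     theta = 0.4, base_int = 0.25, ratio = 0.6, n_chromo = 0L,
                     chromo_contrast = 0, z0 = 2.5, cy2 = NA, cx2 = NA,
                     a2 = NA, b2 = NA, theta2 = NA)
  fld <- render_field(pars, cfg, seed = 3L)
  proj <- max_project(fld$stacks$RFP)
  inside <- fld$ground_truth$mask == 1L
  expect_true(all(abs(proj[inside] - 0.25) < 1e-12))
  expect_true(all(proj[!inside] == 0))
  # GFP is the RFP pattern scaled by the nucleus ratio
  expect_equal(max_project(fld$stacks$GFP)[inside], 0.6 * proj[inside],
               tolerance = 1e-12)
})

test_that("chromocenter contrast raises within-nucleus intensity dispersion", {
  base <- list(field_size_px = c(128L, 128L), n_zplanes = 4L,
               bias_field_amplitude = 0,
               noise = list(poisson_gain = 0, gaussian_sd = 0),
               background = 0)
  pars <- data.frame(id = 1L, class = "good", cy = 64, cx = 64, a = 16, b = 13,
                     theta = 0, base_int = 0.25, ratio = 1, n_chromo = 6L,
                     chromo_contrast = 0, z0 = 2.5, cy2 = NA, cx2 = NA,
                     a2 = NA, b2 = NA, theta2 = NA)
  sds <- vapply(c(0, 5), function(ctr) {
    cfg <- do.call(sim_config, base)
    p <- pars; p$chromo_contrast <- ctr
    fld <- render_field(p, cfg, seed = 5L)
    proj <- max_project(fld$stacks$RFP)
    stats::sd(proj[fld$ground_truth$mask == 1L])
  }, numeric(1))
  expect_lt(sds[1], 1e-12)
  expect_gt(sds[2], sds[1])
})

test_that("heterogeneity scaling monotonically widens parameter dispersion", {
  vars <- vapply(c(0.5, 2), function(h) {
    cfg <- sim_config(nuclei_per_field_mean = 400, heterogeneity_scale = h,
                      field_size_px = c(2048L, 2048L),
                      distractor_rates = c(truncated = 0, merged = 0, debris = 0))
    p <- sample_population(cfg, 0L, seed = 99L)
    stats::var(log(p$a))
  }, numeric(1))
  expect_gt(vars[2], vars[1])
})

test_that("time-course manifest enumerates wells, fields, days and conditions", {
  cfg <- sim_config(field_size_px = c(64L, 64L), n_zplanes = 2L,
                    n_wells = 2L, n_fields_per_well = 2L, days = c(0L, 5L),
                    ratio_mean = c(1, 0.3), heterogeneity_scale = c(1, 0.5),
                    chromocenter_contrast = c(0.6, 1.4),
                    nuclei_per_field_mean = 1,
                    distractor_rates = c(truncated = 0, merged = 0, debris = 0))
  sim <- simulate_timecourse(cfg)
  expect_equal(nrow(sim$manifest), 8L)
  two <- simulate_timecourse(cfg, conditions = list(
    "Gamborg+H" = list(),
    "Gamborg-H" = list(heterogeneity_scale = stats::setNames(c(1, 0.35), c("0", "5")))))
  expect_equal(nrow(two$manifest), 16L)
  expect_setequal(unique(two$manifest$condition), c("Gamborg+H", "Gamborg-H"))
})

test_that("on-disk image sets round-trip through 16-bit TIFF", {
  cfg <- sim_config(field_size_px = c(64L, 64L), n_zplanes = 3L,
                    n_wells = 1L, n_fields_per_well = 1L, days = c(0L),
                    ratio_mean = 1, heterogeneity_scale = 1,
                    chromocenter_contrast = 1, nuclei_per_field_mean = 2)
  td <- file.path(tempdir(), "sim-rt")
  sim <- simulate_timecourse(cfg, out_dir = td)
  expect_true(file.exists(file.path(td, "manifest.csv")))
  expect_true(file.exists(file.path(td, "config.json")))
  back <- read_field_tiffs(sim$manifest$path_stem[1])
  expect_equal(dim(back$stacks$RFP), c(64L, 64L, 3L))
  expect_lt(max(abs(back$stacks$RFP - pmin(sim$fields[[1]]$stacks$RFP, 1))),
            1 / 65535)
  expect_identical(back$ground_truth$mask, sim$fields[[1]]$ground_truth$mask)
  unlink(td, recursive = TRUE)
})
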