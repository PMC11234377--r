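# Feature registry and the morphology/intensity/texture measurements,
# each checked against analytic cases or an independent brute-force oracle.

test_that("registry flags positional features as analysis-ineligible", {
  reg <- feature_registry()
  expect_false(any(duplicated(reg$name)))
  off <- reg$name[!reg$analysis_eligible]
  expect_setequal(off, c("Morphology_centroid_x", "Morphology_centroid_y",
                         "Morphology_orientation"))
})

test_that("morphology descriptors are exact on analytic shapes", {
  d <- fx_disk_coords(40, 50, 50)
  m <- measure_morphology(d$rows, d$cols)
  expect_gt(m[["circularity"]], 0.9); expect_lt(m[["circularity"]], 1.1)
  expect_lt(m[["elongation"]], 0.05)
  expect_equal(m[["equivalent_diameter"]], sqrt(4 * m[["area"]] / pi))
  expect_gt(m[["solidity"]], 0.95)

  g <- expand.grid(rows = 1:10, cols = 1:40)
  r <- measure_morphology(g$rows, g$cols)
  expect_equal(r[["extent"]], 1.0)
  expect_equal(r[["aspect_ratio"]], 4, tolerance = 0.02)
  expect_equal(r[["area"]], 400)
})

test_that("morphology is invariant to 90-degree rotation except position", {
  set.seed(3)
  d <- fx_disk_coords(15, 40, 40)
  keep <- (d$rows - 40)^2 / 225 + (d$cols - 40)^2 / 100 <= 1
  rows <- d$rows[keep]; cols <- d$cols[keep]
  m1 <- measure_morphology(rows, cols)
  m2 <- measure_morphology(cols, 81 - rows)   # rotate 90 degrees
  varying <- c("orientation", "centroid_x", "centroid_y")
  for (nm in setdiff(names(m1), varying))
    expect_equal(m2[[nm]], m1[[nm]], tolerance = 0.02, label = nm)
})

test_that("intensity statistics match the brute-force oracle", {
  expect_equal(unname(measure_intensity(rep(7, 30))),
               c(7, 0, 7, 7, 210, 7, 0, 7, 7, 7, 7, 0))
  v <- as.numeric(1:100)
  mi <- measure_intensity(v)
  expect_equal(mi[["p25"]], 25.75)
  expect_equal(mi[["p75"]], 75.25)
  set.seed(9)
  for (i in 1:3) {
    x <- rlnorm(57)
    expect_equal(measure_intensity(x), oracle_intensity(x), tolerance = 1e-12)
  }
})

test_that("LBP histograms are normalised and match the per-pixel oracle", {
  cst <- matrix(5, 16, 16)
  h <- measure_lbp(cst, rep(1:16, 16), rep(1:16, each = 16), radii = 1:3)
  for (r in 1:3) {
    hr <- h[(r - 1) * 10 + 1:10]
    expect_equal(hr[9], 1)                    # all-neighbours-ge pattern
    expect_equal(sum(hr), 1, tolerance = 1e-9)
  }
  set.seed(21)
  img <- matrix(runif(256), 16, 16)
  rows <- rep(1:16, 16); cols <- rep(1:16, each = 16)
  got <- measure_lbp(img, rows, cols, radii = 1:3)
  for (r in 1:3)
    expect_equal(got[(r - 1) * 10 + 1:10], oracle_lbp_hist(img, r),
                 tolerance = 1e-12)
  # no eligible pixel -> missing, flagged as NA
  small <- measure_lbp(img, 8L, 8L, radii = 8)
  expect_true(all(is.na(small)))
})

test_that("TAS histograms match brute-force neighbour counting", {
  # constant image, window W1: all pixels white; interior pixels have 8 white
  # neighbours so bin 8 dominates
  sq <- expand.grid(rows = 3:14, cols = 3:14)
  cst <- matrix(1, 16, 16)
  tv <- measure_tas(cst, sq$rows, sq$cols)
  w1_orig <- tv[1:9]
  expect_equal(w1_orig[9], 100 / 144)        # 10x10 interior of a 12x12 square
  expect_equal(which.max(w1_orig), 9L)
  # every 9-bin histogram sums to 1 or is all zero
  sums <- vapply(1:6, function(k) sum(tv[(k - 1) * 9 + 1:9]), numeric(1))
  expect_true(all(abs(sums - 1) < 1e-9 | sums == 0))
  set.seed(31)
  img <- matrix(runif(144), 12, 12)
  g <- expand.grid(rows = 2:11, cols = 2:11)
  maskm <- matrix(FALSE, 12, 12); maskm[cbind(g$rows, g$cols)] <- TRUE
  expect_equal(measure_tas(img, g$rows, g$cols),
               oracle_tas(img, maskm), tolerance = 1e-12)
})

test_that("Gabor responses are linear, orientation-symmetric and null on flats", {
  g <- expand.grid(rows = 9:24, cols = 9:24)
  cst <- matrix(0.7, 32, 32)
  expect_lt(max(measure_gabor(cst, g$rows, g$cols)), 1e-9)
  stripes_h <- matrix(sin(2 * pi * (1:32) / 8), 32, 32)            # vary by row
  stripes_v <- matrix(sin(2 * pi * (1:32) / 8), 32, 32, byrow = TRUE)
  gh <- measure_gabor(stripes_h, g$rows, g$cols)
  gv <- measure_gabor(stripes_v, g$rows, g$cols)
  expect_equal(gh, gv, tolerance = 1e-9)
  expect_equal(measure_gabor(2 * stripes_h, g$rows, g$cols), 2 * gh,
               tolerance = 1e-9)
})

test_that("Hu invariants are translation/rotation invariant and match the oracle", {
  set.seed(41)
  img <- matrix(0, 40, 40)
  blob <- fx_disk_coords(8, 15, 15)
  img[cbind(blob$rows, blob$cols)] <- runif(nrow(blob)) + 0.5
  h1 <- measure_hu(img, blob$rows, blob$cols)
  sh <- matrix(0, 40, 40)
  sh[cbind(blob$rows + 10, blob$cols + 12)] <- img[cbind(blob$rows, blob$cols)]
  expect_equal(measure_hu(sh, blob$rows + 10, blob$cols + 12), h1,
               tolerance = 1e-6)
  rot <- matrix(0, 40, 40)                    # 90-degree rotation
  rot[cbind(blob$cols, 41 - blob$rows)] <- img[cbind(blob$rows, blob$cols)]
  expect_equal(measure_hu(rot, blob$cols, 41 - blob$rows), h1, tolerance = 1e-3)
  maskm <- matrix(FALSE, 40, 40); maskm[cbind(blob$rows, blob$cols)] <- TRUE
  expect_equal(unname(measure_hu(img, blob$rows, blob$cols)),
               oracle_hu(img, maskm), tolerance = 1e-10)
  expect_error(measure_hu(img * 0, blob$rows, blob$cols), "zero total")
})

test_that("extraction fills the registry columns from the unsmoothed raster", {
  img <- fx_disk_image(96, 12, 48, 48, 0.5)
  set.seed(51)
  img <- img + matrix(runif(96 * 96, 0, 0.01), 96, 96)
  fi <- field_image(list(RFP = img, GFP = 0.4 * img), fx_meta())
  mk <- segment_nuclei(fi, t_range = c(0.1, 0.4))
  ft <- extract_features(fi, mk)
  expect_equal(nrow(ft), 1L)
  idx <- which(mk$labels == 1L)
  expect_equal(ft$Intensity_RFP_mean, mean(img[idx]))   # raw, not smoothed
  expect_equal(ft$Intensity_GFP_mean, mean((0.4 * img)[idx]))
  expect_equal(ft$Morphology_area, length(idx))
})

test_that("a field with no surviving object yields an empty table with full header", {
  img <- matrix(0, 64, 64); img[30:33, 30:33] <- 1     # 16 px, filtered out
  fi <- field_image(list(RFP = img + 0.001, GFP = img + 0.001), fx_meta())
  mk <- segment_nuclei(fi, t_range = c(0.4, 0.6), kernel_size_px = 1)
  ft <- extract_features(fi, mk)
  expect_equal(nrow(ft), 0L)
  expect_identical(colnames(ft),
                   c(feature_table_metadata_cols(), feature_registry()$name))
})

test_that("stronger chromocenter texture raises coarse-scale LBP non-uniform mass", {
  # population-level monotone response at a radius above the blob size
  mk_field <- function(contrast) {
    cfg <- sim_config(field_size_px = c(384L, 384L), n_zplanes = 3L,
                      nuclei_per_field_mean = 12, bias_field_amplitude = 0,
                      noise = list(poisson_gain = 0, gaussian_sd = 0),
                      chromocenter_contrast = contrast,
                      distractor_rates = c(truncated = 0, merged = 0, debris = 0))
    pars <- sample_population(cfg, 0L, seed = 61L)
    fld <- render_field(pars, cfg, seed = 62L)
    fi <- max_project(fld$stacks, metadata = fx_meta())
    mask <- segment_nuclei(fi, t_range = c(0.03, 0.10))
    extract_features(fi, mask, methods = "lbp")
  }
  lo <- mk_field(0.2); hi <- mk_field(2.0)
  nonuni <- function(ft) mean(ft$LBP_RFP_r05_b9, na.rm = TRUE)
  expect_gt(nonuni(hi), nonuni(lo))
})
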