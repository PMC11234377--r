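# Median collapse, SVD-imputation PCA, prediction ellipses, density maps,
# clustered heatmaps.

mk_table <- function(values, wells, day = 0) {
  # minimal feature table with two eligible features
  data.frame(experiment = "FX", well = wells, roi = 1L, day = day,
             condition = "C", object_id = seq_along(wells), is_border = FALSE,
             Morphology_area = values, Morphology_circularity = rev(values))
}

test_that("matrix preparation collapses by median and scales rows to unit variance", {
  reg <- feature_registry()
  tbl <- rbind(mk_table(c(1, 2, 100), rep("W01", 3)),
               mk_table(c(5, 6, 7), rep("W02", 3)),
               mk_table(c(9, 9, 9), rep("W03", 3)))
  m <- prepare_matrix(tbl, collapse_by = "well", registry = reg)
  expect_equal(ncol(m), 3L)
  # median collapse: {1,2,100} -> 2
  raw_med <- attr(m, "row_center")["Morphology_area"] +
    m["Morphology_area", "W01"] * attr(m, "row_scale")["Morphology_area"]
  expect_equal(unname(raw_med), 2)
  expect_true(all(abs(apply(m, 1, var) - 1) < 1e-9))
  # identical wells collapse to identical columns
  tbl2 <- rbind(mk_table(c(1, 2, 3), rep("W01", 3)),
                mk_table(c(1, 2, 3), rep("W02", 3)),
                mk_table(c(7, 8, 9), rep("W03", 3)))
  m2 <- prepare_matrix(tbl2, collapse_by = "well", registry = reg)
  expect_equal(m2[, "W01"], m2[, "W02"])
  # positional features are excluded
  tbl$Morphology_centroid_x <- rnorm(9)
  m3 <- prepare_matrix(tbl, collapse_by = "well", registry = reg)
  expect_false("Morphology_centroid_x" %in% rownames(m3))
})

test_that("SVD imputation reduces to direct SVD on complete data", {
  set.seed(41)
  x <- outer(rnorm(12), rnorm(6))            # rank 1
  p <- pca_svd_impute(x, n_components = 2)
  expect_equal(p$var_explained[1], 1, tolerance = 1e-12)
  y <- matrix(rnorm(120), 12, 10)
  y <- y - rowMeans(y)
  p2 <- pca_svd_impute(y, n_components = 3)
  s <- svd(y)
  expect_equal(abs(p2$loadings), abs(s$u[, 1:3]), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(abs(p2$scores), abs(s$v[, 1:3] %*% diag(s$d[1:3])),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(diff(p2$var_explained) < 1e-12))
  # deterministic sign: the largest-magnitude loading is positive
  expect_true(all(apply(p2$loadings, 2, function(l) l[which.max(abs(l))] > 0)))
})

test_that("imputed PCA tracks the complete-data scores with 5% missing cells", {
  set.seed(43)
  full <- 5 * outer(rnorm(20), rnorm(10)) + 2 * outer(rnorm(20), rnorm(10)) +
    0.05 * matrix(rnorm(200), 20, 10)
  full <- full - rowMeans(full)
  holes <- full
  miss <- sample(length(full), 10)
  holes[miss] <- NA
  pf <- pca_svd_impute(full, 2)
  ph <- pca_svd_impute(holes, 2)
  expect_true(ph$converged)
  expect_gt(abs(cor(pf$scores[, 1], ph$scores[, 1])), 0.99)
  # a feature with no observed value is rejected
  holes[1, ] <- NA
  expect_error(pca_svd_impute(holes, 2), "at least one observed")
})

test_that("prediction ellipses have the analytic radius and contain their cloud", {
  set.seed(47)
  sc <- matrix(rnorm(2e4), ncol = 2)
  e <- prediction_ellipse(sc, level = 0.95)
  expect_equal(unname(e$semi_axes), rep(sqrt(qchisq(0.95, 2)), 2),
               tolerance = 0.05)
  expect_equal(unname(e$centre), c(0, 0), tolerance = 0.05)
  # level -> 0 collapses onto the centre
  e0 <- prediction_ellipse(sc, level = 0)
  expect_equal(unname(e0$semi_axes), c(0, 0))
  expect_false(any(ellipse_contains(e0, sc + 1)))
  expect_error(prediction_ellipse(sc[1:2, ]), "at least 3")
})

test_that("density maps are percent-normalised and find planted modes", {
  one <- matrix(rep(c(3, 7), each = 12), ncol = 2)
  dm <- density_map(one, grid = c(10L, 10L))
  expect_equal(sum(dm$percent), 100, tolerance = 1e-6)
  expect_equal(max(dm$percent), 100)
  set.seed(53)
  two <- rbind(matrix(rnorm(400, -5, 0.5), ncol = 2),
               matrix(rnorm(400, 5, 0.5), ncol = 2))
  dm2 <- density_map(two, grid = c(30L, 30L))
  expect_equal(sum(dm2$percent), 100, tolerance = 1e-6)
  half <- dm2$x_mid < 0
  expect_gt(max(dm2$smoothed[half, ]), 0.5)
  expect_gt(max(dm2$smoothed[!half, ]), 0.5)
  expect_error(density_map(one[1:5, ]), "at least 10")
})

test_that("heatmap clustering uses correlation distance with average linkage", {
  base <- seq(-1, 1, length.out = 8)
  m <- rbind(a = base, b = base,                     # identical pair
             c = -base + rnorm(8, 0, 1e-3),          # anti-correlated
             d = rnorm(8))
  ch <- cluster_heatmap(m)
  expect_equal(min(ch$heights), 0, tolerance = 1e-12)  # identical rows first
  first_merge <- ch$hclust$merge[1, ]
  expect_setequal(abs(first_merge), c(1, 2))
  expect_true(all(abs(apply(ch$matrix, 1, sd) - 1) < 1e-9))
  # planted two-block structure separates in the leaf order
  set.seed(59)
  sig1 <- rnorm(10); sig2 <- rnorm(10)
  blocks <- rbind(t(replicate(3, sig1 + rnorm(10, 0, 0.1))),
                  t(replicate(3, sig2 + rnorm(10, 0, 0.1))))
  rownames(blocks) <- paste0("f", 1:6)
  cb <- cluster_heatmap(blocks)
  grp <- rep(1:2, each = 3)[cb$order]
  expect_true(all(diff(grp) >= 0) || all(diff(grp) <= 0))
  expect_warning(cluster_heatmap(rbind(m, e = rep(1, 8))), "zero-variance")
})
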