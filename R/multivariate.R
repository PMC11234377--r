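# Multivariate analysis: median-collapsed, row-scaled feature matrices, PCA by
# SVD with iterative imputation of missing cells, prediction ellipses,
# density maps of per-nucleus scores and correlation-clustered heatmaps.

#' Build the feature x sample matrix for multivariate analysis
#'
#' Drops analysis-ineligible columns (positional features and metadata),
#' collapses nuclei to per-group medians (by default one sample per
#' well x day x condition), and centres/scales every feature row to unit
#' variance. Zero-variance rows are dropped with a warning.
#'
#' @param table a `NucleusFeatureTable`.
#' @param collapse_by metadata columns defining the samples.
#' @param registry the [feature_registry()] in use.
#' @param analysis_features_only drop ineligible features (centroids,
#'   orientation) when `TRUE`.
#' @return numeric matrix (features x samples) with attributes `row_center`,
#'   `row_scale` and `samples` (data frame of sample annotations).
#' @export
prepare_matrix <- function(table, collapse_by = c("well", "day", "condition"),
                           registry = feature_registry(),
                           analysis_features_only = TRUE) {
  feats <- registry$name
  if (analysis_features_only) feats <- feats[registry$analysis_eligible]
  feats <- intersect(feats, colnames(table))
  key <- interaction(table[collapse_by], drop = TRUE, sep = "|")
  if (nlevels(key) < 2) stop("need at least 2 samples after collapse")
  med <- vapply(split(seq_len(nrow(table)), key), function(i)
    vapply(feats, function(f) stats::median(table[[f]][i], na.rm = TRUE),
           numeric(1)),
    numeric(length(feats)))
  m <- matrix(med, nrow = length(feats),
              dimnames = list(feats, levels(key)))
  if (all(is.na(m))) stop("all-missing feature matrix")
  ctr <- apply(m, 1, mean, na.rm = TRUE)
  scl <- apply(m, 1, stats::sd, na.rm = TRUE)
  bad <- !is.finite(scl) | scl == 0
  if (any(bad)) {
    warning(sum(bad), " zero-variance feature row(s) dropped")
    m <- m[!bad, , drop = FALSE]
    ctr <- ctr[!bad]; scl <- scl[!bad]
  }
  m <- (m - ctr) / scl
  samples <- as.data.frame(do.call(rbind, strsplit(colnames(m), "|",
                                                   fixed = TRUE)),
                           stringsAsFactors = FALSE)
  names(samples) <- collapse_by
  attr(m, "row_center") <- ctr
  attr(m, "row_scale") <- scl
  attr(m, "samples") <- samples
  m
}

#' PCA by SVD with iterative imputation of missing values
#'
#' Missing cells are initialised to their feature (row) means, then refined by
#' iterating a rank-`n_components` SVD reconstruction until the relative
#' change of the imputed cells falls below `tol`. The final SVD provides
#' loadings (features), scores (samples) and the fraction of variance
#' explained. Component signs follow a deterministic convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param x numeric matrix, features x samples, possibly with `NA`s; rows are
#'   expected centred (see [prepare_matrix()]).
#' @param n_components number of components retained.
#' @param tol relative-change convergence tolerance for imputation.
#' @param max_iter iteration cap; non-convergence returns with a warning flag.
#' @return an object of class `chromatin_pca` with elements `loadings`,
#'   `scores`, `var_explained`, `iterations`, `converged`, plus the scaling
#'   constants carried over from `prepare_matrix` when present.
#' @export
pca_svd_impute <- function(x, n_components = 2L, tol = 1e-6, max_iter = 100L) {
  if (any(rowSums(is.finite(x)) == 0))
    stop("each feature must have at least one observed value")
  k <- min(n_components, dim(x))
  miss <- is.na(x)
  iterations <- 0L
  converged <- TRUE
  x0 <- x
  if (any(miss)) {
    rmeans <- apply(x, 1, mean, na.rm = TRUE)
    x0[miss] <- rmeans[row(x)[miss]]
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      s <- svd(x0, nu = k, nv = k)
      xhat <- s$u %*% (s$d[seq_len(k)] * t(s$v))
      new <- xhat[miss]
      delta <- sqrt(sum((new - x0[miss])^2)) /
        max(sqrt(sum(x0[miss]^2)), .Machine$double.eps)
      x0[miss] <- new
      iterations <- it
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged)
      warning("SVD imputation did not converge in ", max_iter, " iterations")
  }
  s <- svd(x0)
  k <- min(n_components, length(s$d))
  loadings <- s$u[, seq_len(k), drop = FALSE]
  scores <- s$v[, seq_len(k), drop = FALSE] %*% diag(s$d[seq_len(k)], k)
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(loadings) <- list(rownames(x), paste0("PC", seq_len(k)))
  dimnames(scores) <- list(colnames(x), paste0("PC", seq_len(k)))
  structure(list(
    loadings = loadings, scores = scores,
    var_explained = s$d^2 / sum(s$d^2),
    iterations = iterations, converged = converged,
    row_center = attr(x, "row_center"), row_scale = attr(x, "row_scale"),
    samples = attr(x, "samples")
  ), class = "chromatin_pca")
}

#' @export
print.chromatin_pca <- function(x, ...) {
  k <- ncol(x$scores)
  cat(sprintf("PCA (SVD with imputation): %d features, %d samples\n",
              nrow(x$loadings), nrow(x$scores)))
  cat(sprintf("  variance explained: %s\n",
              paste(sprintf("PC%d %.1f%%", seq_len(k),
                            100 * x$var_explained[seq_len(k)]),
                    collapse = ", ")))
  if (x$iterations > 0)
    cat(sprintf("  imputation: %d iteration(s), converged = %s\n",
                x$iterations, x$converged))
  invisible(x)
}

#' Project individual nuclei onto fitted PCA loadings
#'
#' Applies the stored per-feature centring/scaling to each nucleus row and
#' projects onto the sample-level loadings, e.g. to draw per-nucleus density
#' maps in the PC space defined by well medians.
#'
#' @param pca a `chromatin_pca` fitted on a [prepare_matrix()] output.
#' @param table a `NucleusFeatureTable`.
#' @return matrix of per-nucleus scores (nuclei x components).
#' @export
project_nuclei <- function(pca, table) {
  feats <- rownames(pca$loadings)
  if (is.null(pca$row_center))
    stop("pca carries no scaling constants; fit it on a prepare_matrix() output")
  m <- t(as.matrix(table[, feats, drop = FALSE]))
  m <- (m - pca$row_center) / pca$row_scale
  t(m) %*% pca$loadings
}

#' Prediction ellipse for a group of 2-D scores
#'
#' Ellipse expected to contain a fresh observation from the same group with
#' the given probability: centre at the group mean, shape from the sample
#' covariance scaled by `qchisq(level, 2) * (1 + 1/n)`.
#'
#' @param scores n x 2 matrix of group scores (n >= 3).
#' @param level coverage probability.
#' @return object of class `prediction_ellipse`: centre, covariance, radius2,
#'   semi-axes, angle, n, level, and a degeneracy flag.
#' @export
prediction_ellipse <- function(scores, level = 0.95) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 3) stop("need at least 3 observations for a prediction ellipse")
  ctr <- colMeans(scores)
  S <- stats::cov(scores)
  degenerate <- !all(is.finite(S)) || det(S) <= 0
  r2 <- stats::qchisq(level, df = 2) * (1 + 1 / n)
  e <- eigen(S, symmetric = TRUE)
  structure(list(centre = ctr, cov = S, radius2 = r2,
                 semi_axes = sqrt(pmax(e$values, 0) * r2),
                 angle = atan2(e$vectors[2, 1], e$vectors[1, 1]),
                 n = n, level = level, degenerate = degenerate),
            class = "prediction_ellipse")
}

#' Test containment of points in a prediction ellipse
#' @param ellipse a `prediction_ellipse`.
#' @param points m x 2 matrix.
#' @return logical vector.
#' @export
ellipse_contains <- function(ellipse, points) {
  points <- matrix(points, ncol = 2)
  if (ellipse$degenerate)
    return(rowSums((points - rep(ellipse$centre, each = nrow(points)))^2) == 0)
  stats::mahalanobis(points, ellipse$centre, ellipse$cov) <= ellipse$radius2
}

#' Boundary polygon of a prediction ellipse
#' @param ellipse a `prediction_ellipse`.
#' @param n number of boundary points.
#' @return n x 2 matrix.
#' @export
ellipse_points <- function(ellipse, n = 100L) {
  t <- seq(0, 2 * pi, length.out = n)
  circ <- cbind(ellipse$semi_axes[1] * cos(t), ellipse$semi_axes[2] * sin(t))
  rot <- matrix(c(cos(ellipse$angle), sin(ellipse$angle),
                  -sin(ellipse$angle), cos(ellipse$angle)), 2, 2)
  sweep(circ %*% t(rot), 2, ellipse$centre, `+`)
}

#' Density map of per-nucleus PC scores
#'
#' 2-D histogram over the joint PC1-PC2 range normalised so that cell values
#' are percentages of nuclei summing to 100 before smoothing, then Gaussian
#' smoothed for contouring.
#'
#' @param scores m x 2 matrix of per-nucleus scores (m >= 10).
#' @param grid c(nx, ny) histogram resolution.
#' @param smoothing_cells Gaussian sigma in grid cells.
#' @param contour_levels contour percentages.
#' @return list with bin `x_mid`/`y_mid`, `percent` (pre-smoothing),
#'   `smoothed` and `levels`.
#' @export
density_map <- function(scores, grid = c(50L, 50L), smoothing_cells = 1,
                        contour_levels = c(0.1, 0.5, 1, 2, 5)) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 10) stop("need at least 10 nuclei for a density map")
  bx <- seq(min(scores[, 1]), max(scores[, 1]), length.out = grid[1] + 1L)
  by <- seq(min(scores[, 2]), max(scores[, 2]), length.out = grid[2] + 1L)
  # degenerate (point) input: all mass in one cell
  if (bx[1] == bx[length(bx)]) bx <- bx[1] + seq(-0.5, 0.5, length.out = grid[1] + 1L)
  if (by[1] == by[length(by)]) by <- by[1] + seq(-0.5, 0.5, length.out = grid[2] + 1L)
  ix <- findInterval(scores[, 1], bx, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(scores[, 2], by, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0, grid[1], grid[2])
  for (i in seq_len(nrow(scores))) counts[ix[i], iy[i]] <- counts[ix[i], iy[i]] + 1
  percent <- 100 * counts / nrow(scores)
  smoothed <- if (smoothing_cells > 0) {
    half <- max(1L, ceiling(3 * smoothing_cells))
    conv2_replicate(percent, gaussian_kernel(2L * half + 1L, smoothing_cells))
  } else percent
  list(x_mid = (bx[-1] + bx[-length(bx)]) / 2,
       y_mid = (by[-1] + by[-length(by)]) / 2,
       percent = percent, smoothed = smoothed, levels = contour_levels)
}

#' Row-scaled, correlation-clustered heatmap matrix
#'
#' Centres and unit-variance scales each feature row, clusters rows with
#' correlation distance (1 - Pearson r) and average linkage, and returns the
#' scaled matrix with the dendrogram leaf order and merge heights.
#'
#' @param m numeric matrix, features (rows) x groups (columns); >= 2 of each.
#' @return list with `matrix` (scaled, rows in input order), `order` (leaf
#'   order), `hclust` and `heights`.
#' @export
cluster_heatmap <- function(m) {
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 features and >= 2 groups")
  scl <- apply(m, 1, stats::sd)
  bad <- !is.finite(scl) | scl == 0
  if (any(bad)) {
    warning(sum(bad), " zero-variance row(s) dropped")
    m <- m[!bad, , drop = FALSE]
  }
  ms <- t(scale(t(m)))
  d <- stats::as.dist(1 - stats::cor(t(ms)))
  hc <- stats::hclust(d, method = "average")
  list(matrix = ms, order = hc$order, hclust = hc, heights = hc$height)
}
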