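# Texture descriptors: multiscale rotation-invariant uniform local binary
# patterns, threshold adjacency statistics, Gabor filter-bank responses and
# intensity-weighted Hu moment invariants.

# rotation-invariant uniform mapping table for 8-bit codes:
# <=2 circular 0/1 transitions -> popcount (0..8), else the "non-uniform"
# label 9
lbp_riu2_table <- function() {
  codes <- 0:255
  bits <- t(sapply(codes, function(cd) as.integer(intToBits(cd)[1:8])))
  trans <- rowSums(bits != bits[, c(2:8, 1)])
  pop <- rowSums(bits)
  ifelse(trans <= 2, pop, 9L)
}
.lbp_table <- lbp_riu2_table()

# relative tolerance for the neighbour >= centre comparison, so that bilinear
# interpolation round-off on exact ties cannot flip a bit
LBP_TIE_TOL <- 1e-9

#' Rotation-invariant uniform LBP label image for one radius
#'
#' For each requested pixel, samples 8 points on the circle of radius `r`
#' (angles 2*pi*k/8, bilinear interpolation), sets bit k when the neighbour is
#' greater than or equal to the centre (within a small relative tolerance for
#' ties), and maps the 8-bit code through the rotation-invariant uniform
#' scheme to a label in 0..9.
#'
#' @param raster numeric matrix.
#' @param idx linear indices of pixels to label; all must have their full
#'   sampling circle inside the image.
#' @param r circle radius in pixels.
#' @return integer vector of labels 0..9, parallel to `idx`.
#' @keywords internal
lbp_labels_at <- function(raster, idx, r) {
  nr <- nrow(raster)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  centre <- raster[idx]
  tol <- LBP_TIE_TOL * pmax(abs(centre), 1)
  code <- integer(length(idx))
  N <- length(raster)
  for (k in 0:7) {
    ang <- 2 * pi * k / 8
    dy <- round(r * sin(ang), 8)
    dx <- round(r * cos(ang), 8)
    r0 <- floor(dy); fr <- dy - r0
    c0 <- floor(dx); fc <- dx - c0
    rr <- rows + r0; cc <- cols + c0
    i00 <- rr + (cc - 1L) * nr
    # +1 offsets are clamped into range: when an offset is an exact integer
    # the corresponding interpolation weight is zero, so the clamped value
    # never contributes
    i01 <- pmin(i00 + nr, N)
    i10 <- pmin(i00 + 1L, N)
    i11 <- pmin(i00 + nr + 1L, N)
    nb <- (1 - fr) * ((1 - fc) * raster[i00] + fc * raster[i01]) +
      fr * ((1 - fc) * raster[i10] + fc * raster[i11])
    code <- code + bitwShiftL(as.integer(nb >= centre - tol), k)
  }
  .lbp_table[code + 1L]
}

#' Multiscale LBP histograms of one object
#'
#' For each radius, the rotation-invariant uniform LBP labels of the object's
#' eligible pixels (those whose full sampling circle lies inside the image)
#' are collected into a 10-bin histogram normalised to sum 1. Pixels whose
#' circle exits the image are excluded rather than padded. A radius with no
#' eligible pixel yields all-missing values.
#'
#' @param raster numeric matrix (full field, unsmoothed).
#' @param rows,cols pixel coordinates of the object.
#' @param radii circle radii.
#' @return numeric vector of length `10 * length(radii)`, radii-major.
#' @export
measure_lbp <- function(raster, rows, cols, radii = 1:10) {
  nr <- nrow(raster); nc <- ncol(raster)
  out <- numeric(0)
  for (r in radii) {
    elig <- rows > r & rows <= nr - r & cols > r & cols <= nc - r
    if (!any(elig)) {
      out <- c(out, rep(NA_real_, 10))
      next
    }
    idx <- rows[elig] + (cols[elig] - 1L) * nr
    lab <- lbp_labels_at(raster, idx, r)
    h <- tabulate(lab + 1L, nbins = 10L)
    out <- c(out, h / sum(h))
  }
  out
}

# count of white 8-neighbours at every pixel of a logical matrix
neighbour_count8 <- function(white) {
  nr <- nrow(white); nc <- ncol(white)
  w <- matrix(0L, nr + 2L, nc + 2L)
  w[2:(nr + 1L), 2:(nc + 1L)] <- white
  acc <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    acc <- acc + w[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  acc
}

#' Threshold adjacency statistics of one object
#'
#' Binarises the object's pixels with three windows derived from the object
#' mean mu and population SD sigma -- W1 at or above mu, W2 within one sigma
#' of mu, W3 at or above mu + sigma -- and, for both the binary image and its
#' complement within the mask, histograms the number of white 8-neighbours
#' (0..8) over white pixels, normalised to sum 1. An empty white set yields an
#' all-zero histogram. 3 windows x 2 images x 9 bins = 54 values.
#'
#' @param raster numeric matrix (full field, unsmoothed).
#' @param rows,cols pixel coordinates of the object.
#' @return numeric vector of length 54, in registry order.
#' @export
measure_tas <- function(raster, rows, cols) {
  vals <- raster[cbind(rows, cols)]
  mu <- mean(vals)
  sigma <- sqrt(mean((vals - mu)^2))
  r0 <- min(rows); c0 <- min(cols)
  h <- max(rows) - r0 + 1L; w <- max(cols) - c0 + 1L
  inmask <- matrix(FALSE, h, w)
  inmask[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- TRUE
  img <- matrix(0, h, w)
  img[inmask] <- vals
  windows <- list(
    w1 = img >= mu,
    w2 = img >= mu - sigma & img <= mu + sigma,
    w3 = img >= mu + sigma
  )
  out <- numeric(0)
  for (wn in windows) {
    for (variant in c("orig", "comp")) {
      white <- if (variant == "orig") inmask & wn else inmask & !wn
      if (!any(white)) {
        out <- c(out, rep(0, 9))
        next
      }
      counts <- neighbour_count8(white)
      hgram <- tabulate(counts[white] + 1L, nbins = 9L)
      out <- c(out, hgram / sum(hgram))
    }
  }
  out
}

# zero-mean complex Gabor kernel pair at one wavelength/orientation;
# max_half clamps the kernel to the image extent
gabor_kernel <- function(wavelength, theta, sigma = 0.56 * wavelength,
                         max_half = Inf) {
  half <- min(max(2L, as.integer(ceiling(3 * sigma))), max_half)
  g <- seq(-half, half)
  x <- matrix(g, 2 * half + 1, 2 * half + 1, byrow = TRUE)
  y <- matrix(g, 2 * half + 1, 2 * half + 1)
  xr <- x * cos(theta) + y * sin(theta)
  yr <- -x * sin(theta) + y * cos(theta)
  env <- exp(-(xr^2 + yr^2) / (2 * sigma^2))
  even <- env * cos(2 * pi * xr / wavelength)
  odd <- env * sin(2 * pi * xr / wavelength)
  even <- even - mean(even)          # remove DC so flat images respond ~0
  list(even = even, odd = odd)
}

#' Whole-field Gabor magnitude responses
#'
#' For each wavelength: filters the raster with a quadrature Gabor pair at
#' orientations 0, 45, 90 and 135 degrees, takes the pixelwise magnitude and
#' then the pixelwise maximum over orientations.
#'
#' @param raster numeric matrix.
#' @param wavelengths Gabor wavelengths in pixels.
#' @return named list of response matrices, one per wavelength.
#' @export
gabor_response <- function(raster, wavelengths = c(2, 4, 8, 16)) {
  out <- list()
  max_half <- as.integer((min(dim(raster)) - 1) %/% 2)
  for (wl in wavelengths) {
    best <- NULL
    for (theta in c(0, 45, 90, 135) * pi / 180) {
      k <- gabor_kernel(wl, theta, max_half = max_half)
      ev <- conv2_replicate(raster, k$even)
      od <- conv2_replicate(raster, k$odd)
      mag <- sqrt(ev^2 + od^2)
      best <- if (is.null(best)) mag else pmax(best, mag)
    }
    out[[sprintf("w%02d", wl)]] <- best
  }
  out
}

#' Gabor features of one object
#'
#' Mean of the orientation-maximum Gabor magnitude response over the object's
#' pixels, one value per wavelength.
#'
#' @param raster numeric matrix, or a precomputed [gabor_response()] list.
#' @param rows,cols pixel coordinates of the object.
#' @param wavelengths Gabor wavelengths (ignored when a response list is
#'   supplied).
#' @return numeric vector, one value per wavelength.
#' @export
measure_gabor <- function(raster, rows, cols, wavelengths = c(2, 4, 8, 16)) {
  resp <- if (is.list(raster)) raster else gabor_response(raster, wavelengths)
  vapply(resp, function(m) mean(m[cbind(rows, cols)]), numeric(1))
}

#' Hu moment invariants of one object
#'
#' Intensity-weighted central moments of the masked pixels give the seven Hu
#' invariants, reported on the conventional log scale
#' -sign(h) * log10(|h| + 1e-30).
#'
#' @param raster numeric matrix.
#' @param rows,cols pixel coordinates of the object.
#' @return named numeric vector of length 7.
#' @export
measure_hu <- function(raster, rows, cols) {
  w <- raster[cbind(rows, cols)]
  m00 <- sum(w)
  if (m00 <= 0) stop("zero total intensity in object")
  cx <- sum(w * cols) / m00
  cy <- sum(w * rows) / m00
  x <- cols - cx; y <- rows - cy
  mu <- function(p, q) sum(w * x^p * y^q)
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  h <- c(
    n20 + n02,
    (n20 - n02)^2 + 4 * n11^2,
    (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    (n30 + n12)^2 + (n21 + n03)^2,
    (n30 - 3 * n12) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
      (3 * n21 - n03) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2),
    (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
      4 * n11 * (n30 + n12) * (n21 + n03),
    (3 * n21 - n03) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
      (n30 - 3 * n12) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2)
  )
  stats::setNames(-sign(h) * log10(abs(h) + 1e-30), paste0("h", 1:7))
}
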