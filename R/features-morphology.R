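# Morphology descriptors of a segmented object (mask-derived, channel-shared).

# Kulpa-corrected boundary length from an 8-connected contour trace:
# 0.948 per straight step, 1.340 per diagonal step. This makes digitised
# disks measure ~2*pi*r, so circularity of a disk is ~1.
contour_perimeter <- function(obj) {
  oc <- EBImage::ocontour(obj)[[1]]
  if (nrow(oc) < 2) return(1)
  d <- rbind(diff(oc), oc[1, ] - oc[nrow(oc), ])
  steps <- abs(d[, 1]) + abs(d[, 2])
  straight <- sum(steps == 1)
  diagonal <- sum(steps == 2)
  # non-adjacent jumps (can occur on one-pixel-wide spurs): Euclidean length
  other <- steps > 2
  0.948 * straight + 1.340 * diagonal +
    sum(sqrt(d[other, 1]^2 + d[other, 2]^2))
}

polygon_perimeter <- function(xy) {
  if (nrow(xy) < 2) return(0)
  d <- rbind(diff(xy), xy[1, ] - xy[nrow(xy), ])
  sum(sqrt(d[, 1]^2 + d[, 2]^2))
}

polygon_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Morphology features of one mask object
#'
#' Computes the 16 morphology descriptors of a binary object: area, perimeter
#' (Kulpa-corrected contour length), equivalent diameter, major/minor axis
#' lengths and eccentricity from binary central moments, circularity
#' (4*pi*A/P^2), roundness (4*A/(pi*major^2)), elongation (1 - minor/major),
#' convexity (convex-hull perimeter / perimeter), solidity (area / convex-hull
#' area), extent (area / bounding-box area), aspect ratio, orientation and
#' centroid. Dimensionless shape values land in [0, ~1.1] (rasterisation
#' slack).
#'
#' @param rows,cols integer pixel coordinates of the object (full-image frame).
#' @return named numeric vector of length 16, in registry order.
#' @export
measure_morphology <- function(rows, cols) {
  n <- length(rows)
  if (n < 1) stop("empty object")
  area <- n
  cy <- mean(rows); cx <- mean(cols)
  mu20 <- mean((cols - cx)^2)
  mu02 <- mean((rows - cy)^2)
  mu11 <- mean((cols - cx) * (rows - cy))
  common <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- (mu20 + mu02) / 2 + common
  l2 <- (mu20 + mu02) / 2 - common
  major <- 4 * sqrt(max(l1, 0))
  minor <- 4 * sqrt(max(l2, 0))
  ecc <- if (l1 > 0) sqrt(pmax(1 - l2 / l1, 0)) else 0
  orientation <- 0.5 * atan2(2 * mu11, mu20 - mu02)

  # crop with a 1-px pad for the contour trace
  r0 <- min(rows); c0 <- min(cols)
  obj <- matrix(0L, max(rows) - r0 + 3L, max(cols) - c0 + 3L)
  obj[cbind(rows - r0 + 2L, cols - c0 + 2L)] <- 1L
  perim <- contour_perimeter(obj)

  hull_idx <- grDevices::chull(cols, rows)
  hull <- cbind(cols[hull_idx], rows[hull_idx])
  hull_perim <- polygon_perimeter(hull)
  # hull polygon runs through pixel centres; widen by half the boundary to
  # approximate the pixel-set hull area (Pick-style correction)
  hull_area <- polygon_area(hull) + hull_perim / 2 + 1

  bbox_area <- (max(rows) - min(rows) + 1) * (max(cols) - min(cols) + 1)
  c(
    area = area,
    perimeter = perim,
    equivalent_diameter = sqrt(4 * area / pi),
    major_axis_length = major,
    minor_axis_length = minor,
    eccentricity = ecc,
    circularity = 4 * pi * area / perim^2,
    roundness = if (major > 0) 4 * area / (pi * major^2) else 1,
    elongation = if (major > 0) 1 - minor / major else 0,
    convexity = if (perim > 0) hull_perim / perim else 1,
    solidity = area / max(hull_area, area),
    extent = area / bbox_area,
    aspect_ratio = if (minor > 0) major / minor else Inf,
    orientation = orientation,
    centroid_x = cx,
    centroid_y = cy
  )
}
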