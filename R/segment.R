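# Nucleus segmentation on the total-chromatin (RFP) channel:
# Gaussian smoothing -> ranged Otsu -> binarise -> fill holes -> size filter
# -> 8-connected labelling -> border flags.

#' Gaussian smoothing with an odd, truncated kernel
#'
#' Smooths a raster with a normalised Gaussian kernel of the given size,
#' sigma = size / 4, truncated to size x size, with replicated borders.
#'
#' @param raster numeric matrix.
#' @param kernel_size_px odd integer kernel size >= 1.
#' @return smoothed matrix of the same dimensions.
#' @export
gaussian_smooth <- function(raster, kernel_size_px = 5L) {
  if (length(kernel_size_px) != 1L || kernel_size_px < 1 ||
      kernel_size_px %% 2 == 0)
    stop("kernel size must be an odd integer >= 1")
  if (kernel_size_px == 1L) return(raster)
  k <- gaussian_kernel(as.integer(kernel_size_px), kernel_size_px / 4)
  conv2_replicate(raster, k)
}

#' Otsu threshold restricted to a user-defined range
#'
#' Bins the raster into `n_bins` equal-width bins over its full value range
#' and returns the interior bin edge within `[t_min, t_max]` that maximises
#' the between-class variance of the resulting two-class split. Ties are
#' broken toward the lower threshold.
#'
#' @param raster numeric matrix.
#' @param t_min,t_max admissible threshold range (t_min < t_max).
#' @param n_bins number of histogram bins.
#' @return the selected threshold (a bin edge).
#' @export
ranged_otsu <- function(raster, t_min = -Inf, t_max = Inf, n_bins = 256L) {
  x <- as.vector(raster)
  x <- x[is.finite(x)]
  if (!length(x)) stop("degenerate histogram: no finite pixels")
  if (t_min >= t_max) stop("degenerate histogram: empty threshold range")
  rmin <- min(x); rmax <- max(x)
  if (rmin == rmax) stop("degenerate histogram: constant raster")
  edges <- seq(rmin, rmax, length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  cand <- edges[2:n_bins]                       # interior edges
  admissible <- cand >= t_min & cand <= t_max
  if (!any(admissible)) stop("degenerate histogram: no admissible threshold")
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  n <- sum(counts)
  w0 <- cumsum(counts)[1:(n_bins - 1L)] / n     # class: bins 1..k vs rest
  m0 <- cumsum(counts * mids)[1:(n_bins - 1L)] / n
  mt <- sum(counts * mids) / n
  w1 <- 1 - w0
  sb <- ifelse(w0 > 0 & w1 > 0, (mt * w0 - m0)^2 / (w0 * w1), 0)
  sb[!admissible] <- -Inf
  cand[which.max(sb)]                           # which.max takes first on ties
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so diagonally
# adjacent labels are merged with union-find
label_8conn <- function(bw) {
  lab <- EBImage::bwlabel(bw)
  n <- max(lab)
  if (n < 2) { storage.mode(lab) <- "integer"; return(lab) }
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]          # \ diagonal
  c_ <- lab[-1, -nc]; d <- lab[-nr, -1]         # / diagonal
  pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                 cbind(as.vector(c_), as.vector(d)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  remap <- match(root, sort(unique(root)))
  out <- matrix(0L, nr, nc)
  nz <- lab > 0
  out[nz] <- remap[lab[nz]]
  out
}

#' Segment nuclei in a field image
#'
#' Applies Gaussian smoothing, ranged Otsu thresholding on the total-chromatin
#' channel, binarisation (strictly above threshold), binary hole filling,
#' removal of connected components below `min_area_px` (strict), 8-connected
#' labelling with contiguous labels, and flags objects touching any image
#' edge.
#'
#' @param field a `field_image` (or a plain matrix treated as the RFP
#'   channel).
#' @param t_range length-2 numeric Otsu search range; default spans the full
#'   smoothed-intensity range.
#' @param min_area_px objects with area strictly below this are removed.
#' @param kernel_size_px smoothing kernel size passed to [gaussian_smooth()].
#' @param channel channel used for segmentation.
#' @return an object of class `label_mask`: list with integer matrix `labels`
#'   (0 = background, 1..N contiguous), data frame `objects` (label, area,
#'   bbox, is_border) and the threshold used.
#' @export
segment_nuclei <- function(field, t_range = NULL, min_area_px = 200L,
                           kernel_size_px = 5L, channel = "RFP") {
  raster <- if (inherits(field, "field_image")) {
    if (!channel %in% names(field$channels))
      stop("channel '", channel, "' not present in field")
    field$channels[[channel]]
  } else field
  sm <- gaussian_smooth(raster, kernel_size_px)
  if (is.null(t_range)) t_range <- range(sm)
  thr <- ranged_otsu(sm, t_range[1], t_range[2])
  bw <- sm > thr
  bw <- EBImage::fillHull(bw) > 0
  lab <- label_8conn(bw)
  areas <- tabulate(lab[lab > 0], nbins = max(lab, 1L))
  keep <- which(areas >= min_area_px)
  remap <- integer(max(lab, 1L))
  remap[keep] <- seq_along(keep)
  nz <- lab > 0
  lab[nz] <- remap[lab[nz]]
  objects <- label_mask_objects(lab)
  structure(list(labels = lab, objects = objects, threshold = thr,
                 min_area_px = min_area_px),
            class = "label_mask")
}

# per-object bookkeeping: area, bbox, border flag
label_mask_objects <- function(lab) {
  n <- max(lab)
  if (n == 0)
    return(data.frame(label = integer(0), area = integer(0),
                      bbox_rmin = integer(0), bbox_rmax = integer(0),
                      bbox_cmin = integer(0), bbox_cmax = integer(0),
                      is_border = logical(0)))
  idx <- which(lab > 0)
  l <- lab[idx]
  r <- ((idx - 1L) %% nrow(lab)) + 1L
  cc <- ((idx - 1L) %/% nrow(lab)) + 1L
  data.frame(
    label = seq_len(n),
    area = tabulate(l, nbins = n),
    bbox_rmin = vapply(split(r, l), min, integer(1)),
    bbox_rmax = vapply(split(r, l), max, integer(1)),
    bbox_cmin = vapply(split(cc, l), min, integer(1)),
    bbox_cmax = vapply(split(cc, l), max, integer(1)),
    is_border = vapply(seq_len(n), function(i) {
      any(r[l == i] %in% c(1L, nrow(lab))) | any(cc[l == i] %in% c(1L, ncol(lab)))
    }, logical(1)),
    row.names = NULL
  )
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("label_mask: %d objects (threshold %.4g, min area %d px, %d border)\n",
              nrow(x$objects), x$threshold, x$min_area_px,
              sum(x$objects$is_border)))
  invisible(x)
}

#' Write a label mask and its object table to disk
#' @param mask a `label_mask`.
#' @param stem output path stem; writes `<stem>_mask.tif` (16-bit) and
#'   `<stem>_objects.csv`.
#' @export
write_label_mask <- function(mask, stem) {
  tiff::writeTIFF(mask$labels / 65535, paste0(stem, "_mask.tif"),
                  bits.per.sample = 16L)
  utils::write.csv(mask$objects, paste0(stem, "_objects.csv"), row.names = FALSE)
  invisible(stem)
}
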