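# Stack projection and retrospective illumination correction.

#' Construct a field image
#'
#' A field image holds one 2-D non-negative raster per channel plus
#' acquisition metadata. All channel rasters must share dimensions.
#'
#' @param channels named list of numeric matrices.
#' @param metadata named list; must contain experiment, well, roi, day and
#'   condition.
#' @param pixel_size_um pixel pitch in micrometres.
#' @return an object of class `field_image`.
#' @export
field_image <- function(channels, metadata, pixel_size_um = NA_real_) {
  stopifnot(is.list(channels), length(channels) >= 1, !is.null(names(channels)))
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1L) stop("all channel rasters must share dimensions")
  need <- c("experiment", "well", "roi", "day", "condition")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("incomplete metadata, missing: ",
                         paste(miss, collapse = ", "))
  structure(list(channels = channels, metadata = metadata,
                 pixel_size_um = pixel_size_um),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("field_image: %d x %d px, channels [%s]\n", d[1], d[2],
              paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  %s / %s / roi %s / day %s / %s\n", x$metadata$experiment,
              x$metadata$well, x$metadata$roi, x$metadata$day,
              x$metadata$condition))
  invisible(x)
}

#' Maximum intensity projection of a z-stack
#'
#' Projects a per-channel z-stack to a single raster per channel, taking the
#' elementwise maximum over z-planes.
#'
#' @param stack either a named list of h x w x z arrays (one per channel), a
#'   single such array, or a list of equally sized plane matrices.
#' @param metadata,pixel_size_um passed to [field_image()] when `stack` is a
#'   per-channel list; otherwise a plain matrix is returned.
#' @return a `field_image` (multi-channel input) or a matrix.
#' @export
max_project <- function(stack, metadata = NULL, pixel_size_um = NA_real_) {
  project1 <- function(s) {
    if (is.array(s) && length(dim(s)) == 3L) {
      apply(s, c(1, 2), max)
    } else if (is.list(s)) {
      if (length(s) < 1L) stop("stack must contain at least one z-plane")
      d <- unique(lapply(s, dim))
      if (length(d) != 1L) stop("ragged stack: plane dimensions differ")
      Reduce(pmax, s)
    } else if (is.matrix(s)) {
      s
    } else stop("unsupported stack representation")
  }
  is_stack3d <- function(x) is.array(x) && length(dim(x)) == 3L
  multi <- is.list(stack) && !is.null(names(stack)) &&
    all(vapply(stack, function(x) is_stack3d(x) || is.list(x), logical(1)))
  if (multi) {
    chans <- lapply(stack, project1)
    if (is.null(metadata)) return(chans)
    return(field_image(chans, metadata, pixel_size_um))
  }
  project1(stack)
}

#' Retrospective illumination correction across fields
#'
#' Estimates, per channel, a multiplicative bias as the heavily smoothed
#' per-pixel mean across all fields, normalised to mean 1, and divides it out
#' of every field. The bias is floored at 1e-3 of its mean so corrected values
#' stay finite.
#'
#' @param fields list of `field_image` objects sharing dimensions.
#' @param smoothing_sigma_px Gaussian sigma (pixels) of the bias smoother.
#' @return list with `fields` (corrected) and `bias` (named list of bias
#'   rasters per channel).
#' @export
correct_illumination <- function(fields, smoothing_sigma_px = 50) {
  stopifnot(length(fields) >= 1)
  chans <- names(fields[[1]]$channels)
  d <- dim(fields[[1]]$channels[[1]])
  bias <- list()
  for (ch in chans) {
    mats <- lapply(fields, function(f) f$channels[[ch]])
    if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1))))
      stop("fields must share dimensions for illumination correction")
    avg <- Reduce(`+`, mats) / length(mats)
    if (length(fields) == 1L && stats::var(as.vector(avg)) == 0) {
      warning("single constant field: degenerate bias, passing through")
      b <- matrix(1, d[1], d[2])
    } else {
      b <- smooth_gaussian_wide(avg, smoothing_sigma_px)
      b <- b / mean(b)
      b <- pmax(b, 1e-3)
    }
    bias[[ch]] <- b
  }
  corrected <- lapply(fields, function(f) {
    for (ch in chans) f$channels[[ch]] <- f$channels[[ch]] / bias[[ch]]
    f
  })
  list(fields = corrected, bias = bias)
}
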