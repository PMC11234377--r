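# Per-channel intensity statistics over the masked pixels of one object.

#' Intensity features of one object
#'
#' Twelve distribution statistics of the masked pixel values: mean, population
#' standard deviation, min, max, sum, median, median absolute deviation
#' (unscaled), the 5th/25th/75th/95th percentiles (linear interpolation) and
#' the range.
#'
#' @param values numeric vector of masked pixel intensities.
#' @return named numeric vector of length 12, in registry order.
#' @export
measure_intensity <- function(values) {
  if (!length(values)) stop("empty object")
  m <- mean(values)
  q <- stats::quantile(values, c(0.05, 0.25, 0.75, 0.95), names = FALSE,
                       type = 7)
  c(
    mean = m,
    std = sqrt(mean((values - m)^2)),
    min = min(values),
    max = max(values),
    sum = sum(values),
    median = stats::median(values),
    mad = stats::median(abs(values - stats::median(values))),
    p05 = q[1], p25 = q[2], p75 = q[3], p95 = q[4],
    range = max(values) - min(values)
  )
}
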