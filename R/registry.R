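# The authoritative 370-feature registry: 16 shared morphology features plus,
# per channel, 12 intensity statistics, 7 Hu moments, 4 Gabor responses,
# 54 threshold adjacency statistics and 100 local binary pattern bins
# (10 radii x 10 bins). Totals are asserted at construction: 193 metrics per
# channel (channel-specific plus shared morphology) and 370 overall.

MORPHOLOGY_NAMES <- c(
  "area", "perimeter", "equivalent_diameter", "major_axis_length",
  "minor_axis_length", "eccentricity", "circularity", "roundness",
  "elongation", "convexity", "solidity", "extent", "aspect_ratio",
  "orientation", "centroid_x", "centroid_y"
)

INTENSITY_NAMES <- c("mean", "std", "min", "max", "sum", "median", "mad",
                     "p05", "p25", "p75", "p95", "range")

#' The feature registry
#'
#' Returns the ordered list of feature definitions: name, family (morphology,
#' intensity, texture), method (morphology, intensity, hu, gabor, tas, lbp),
#' channel (RFP, GFP or shared) and analysis eligibility. Positional features
#' (centroids, orientation) are flagged ineligible for multivariate and
#' entropy analysis.
#'
#' @param channels channel names, in order.
#' @return data frame with one row per feature, in canonical column order.
#' @export
feature_registry <- function(channels = c("RFP", "GFP")) {
  morph <- data.frame(
    name = paste0("Morphology_", MORPHOLOGY_NAMES),
    family = "morphology", method = "morphology", channel = "shared",
    analysis_eligible = !MORPHOLOGY_NAMES %in%
      c("centroid_x", "centroid_y", "orientation"),
    stringsAsFactors = FALSE
  )
  per_channel <- function(ch) {
    rbind(
      data.frame(name = sprintf("Intensity_%s_%s", ch, INTENSITY_NAMES),
                 family = "intensity", method = "intensity", channel = ch,
                 analysis_eligible = TRUE, stringsAsFactors = FALSE),
      data.frame(name = sprintf("Hu_%s_h%d", ch, 1:7),
                 family = "texture", method = "hu", channel = ch,
                 analysis_eligible = TRUE, stringsAsFactors = FALSE),
      data.frame(name = sprintf("Gabor_%s_w%02d", ch, c(2L, 4L, 8L, 16L)),
                 family = "texture", method = "gabor", channel = ch,
                 analysis_eligible = TRUE, stringsAsFactors = FALSE),
      data.frame(name = as.vector(t(outer(
        sprintf("TAS_%s_w%d", ch, 1:3),
        as.vector(t(outer(c("orig", "comp"), sprintf("n%d", 0:8), paste, sep = "_"))),
        paste, sep = "_"))),
        family = "texture", method = "tas", channel = ch,
        analysis_eligible = TRUE, stringsAsFactors = FALSE),
      data.frame(name = as.vector(t(outer(
        sprintf("LBP_%s_r%02d", ch, 1:10), sprintf("b%d", 0:9), paste, sep = "_"))),
        family = "texture", method = "lbp", channel = ch,
        analysis_eligible = TRUE, stringsAsFactors = FALSE)
    )
  }
  reg <- rbind(morph, do.call(rbind, lapply(channels, per_channel)))
  rownames(reg) <- NULL
  # registry arithmetic: 16 + 2 x (12 + 7 + 4 + 54 + 100) = 370
  stopifnot(
    sum(reg$channel == "shared") == 16L,
    all(vapply(channels, function(ch) sum(reg$channel == ch), integer(1)) == 177L),
    all(vapply(channels, function(ch)
      sum(reg$channel %in% c(ch, "shared")), integer(1)) == 193L),
    nrow(reg) == 16L + 177L * length(channels)
  )
  if (length(channels) == 2L) stopifnot(nrow(reg) == 370L)
  reg
}

#' Metadata columns of a nucleus feature table
#' @export
feature_table_metadata_cols <- function() {
  c("experiment", "well", "roi", "day", "condition", "object_id", "is_border")
}

#' Export the registry as JSON
#' @param registry a [feature_registry()] data frame.
#' @param path output path.
#' @export
write_registry_json <- function(registry, path) {
  jsonlite::write_json(registry, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
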