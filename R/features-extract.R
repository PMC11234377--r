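# Per-nucleus feature extraction: assembles the registry's 370 columns from
# the mask (morphology) and the unsmoothed, illumination-corrected rasters of
# both channels (intensity + texture).

#' Extract the feature registry for every object of a field
#'
#' Computes, per segmented object, the 16 shared morphology features from the
#' label mask and the 177 per-channel features (12 intensity, 7 Hu, 4 Gabor,
#' 54 TAS, 100 LBP) from each channel raster. Texture and intensity are
#' measured on the unsmoothed (illumination-corrected) rasters; the smoothing
#' used for segmentation never enters the measurements.
#'
#' @param field a `field_image` whose channels match the registry.
#' @param mask a `label_mask` with the same dimensions.
#' @param registry a [feature_registry()]; its rows define the column set.
#' @param methods subset of feature methods to compute; columns of excluded
#'   methods are emitted as `NA` so the table always carries the full
#'   registry header.
#' @return a `NucleusFeatureTable` data frame: metadata columns (experiment,
#'   well, roi, day, condition, object_id, is_border) followed by one column
#'   per registry feature, in registry order.
#' @export
extract_features <- function(field, mask, registry = feature_registry(),
                             methods = c("morphology", "intensity", "hu",
                                         "gabor", "tas", "lbp")) {
  channels <- setdiff(unique(registry$channel), "shared")
  if (!all(channels %in% names(field$channels)))
    stop("field channels do not match registry channels")
  lab <- mask$labels
  if (!identical(dim(lab), dim(field$channels[[1]])))
    stop("mask and field dimensions differ")
  meta_cols <- feature_table_metadata_cols()
  n_obj <- max(lab, 0L)

  empty <- as.data.frame(
    stats::setNames(rep(list(numeric(0)), length(registry$name)), registry$name),
    check.names = FALSE)
  meta0 <- data.frame(experiment = character(0), well = character(0),
                      roi = integer(0), day = integer(0),
                      condition = character(0), object_id = integer(0),
                      is_border = logical(0), stringsAsFactors = FALSE)
  if (n_obj == 0) return(cbind(meta0, empty))

  idx <- which(lab > 0)
  l <- lab[idx]
  rows <- ((idx - 1L) %% nrow(lab)) + 1L
  cols <- ((idx - 1L) %/% nrow(lab)) + 1L
  ord <- order(l)
  l <- l[ord]; rows <- rows[ord]; cols <- cols[ord]
  rsplit <- split(rows, l)
  csplit <- split(cols, l)

  out <- matrix(NA_real_, n_obj, nrow(registry),
                dimnames = list(NULL, registry$name))

  if ("morphology" %in% methods) {
    morph <- t(vapply(seq_len(n_obj), function(i)
      measure_morphology(rsplit[[i]], csplit[[i]]), numeric(16)))
    out[, paste0("Morphology_", MORPHOLOGY_NAMES)] <- morph
  }

  for (ch in channels) {
    raster <- field$channels[[ch]]
    if ("intensity" %in% methods) {
      iv <- t(vapply(seq_len(n_obj), function(i)
        measure_intensity(raster[cbind(rsplit[[i]], csplit[[i]])]),
        numeric(12)))
      out[, sprintf("Intensity_%s_%s", ch, INTENSITY_NAMES)] <- iv
    }
    if ("hu" %in% methods) {
      hv <- t(vapply(seq_len(n_obj), function(i)
        measure_hu(raster, rsplit[[i]], csplit[[i]]), numeric(7)))
      out[, sprintf("Hu_%s_h%d", ch, 1:7)] <- hv
    }
    if ("tas" %in% methods) {
      tv <- t(vapply(seq_len(n_obj), function(i)
        measure_tas(raster, rsplit[[i]], csplit[[i]]), numeric(54)))
      out[, grep(sprintf("^TAS_%s_", ch), registry$name, value = TRUE)] <- tv
    }
    if ("gabor" %in% methods) {
      resp <- gabor_response(raster)
      gv <- t(vapply(seq_len(n_obj), function(i)
        measure_gabor(resp, rsplit[[i]], csplit[[i]]), numeric(4)))
      out[, sprintf("Gabor_%s_w%02d", ch, c(2L, 4L, 8L, 16L))] <- gv
    }
    if ("lbp" %in% methods) {
      lv <- t(vapply(seq_len(n_obj), function(i)
        measure_lbp(raster, rsplit[[i]], csplit[[i]]), numeric(100)))
      out[, grep(sprintf("^LBP_%s_", ch), registry$name, value = TRUE)] <- lv
    }
  }

  md <- field$metadata
  meta <- data.frame(experiment = md$experiment, well = md$well,
                     roi = md$roi, day = md$day, condition = md$condition,
                     object_id = seq_len(n_obj),
                     is_border = mask$objects$is_border,
                     stringsAsFactors = FALSE)
  tbl <- cbind(meta, as.data.frame(out, check.names = FALSE))
  if (!identical(colnames(tbl), c(meta_cols, registry$name)))
    stop("feature table columns do not match registry")
  tbl
}

#' Extract and bind feature tables for many fields
#'
#' @param fields list of entries with `field` (a `field_image`) and `mask`
#'   (a `label_mask`), e.g. as assembled by [run_pipeline()].
#' @inheritParams extract_features
#' @return one `NucleusFeatureTable` covering all fields.
#' @export
extract_features_all <- function(fields, registry = feature_registry(),
                                 methods = c("morphology", "intensity", "hu",
                                             "gabor", "tas", "lbp")) {
  do.call(rbind, lapply(fields, function(fm)
    extract_features(fm$field, fm$mask, registry, methods)))
}
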