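# End-to-end orchestration: simulate (or load) -> project -> correct
# illumination -> segment -> extract features -> QC -> ratio, PCA and entropy
# analyses, with provenance-stamped CSV artifacts.

#' Pipeline configuration
#'
#' Collects every stage parameter with defaults matching the canonical
#' analysis (5-px smoothing kernel, strict <200 px size filter, strict
#' >5000 px giant filter, 95% prediction ellipses, grouping by day).
#'
#' @param sim a [sim_config()] driving simulation, or `NULL` to read images
#'   from `input_dir` (a directory written by [simulate_timecourse()]).
#' @param input_dir experiment directory when `sim` is `NULL`.
#' @param out_dir artifact directory; `NULL` keeps everything in memory.
#' @param conditions condition overrides passed to [simulate_timecourse()].
#' @param kernel_size_px,otsu_range,min_area_px segmentation parameters.
#'   `otsu_range` is the user-defined Otsu search range; the default sits in
#'   the background-nucleus intensity gap of the simulator's intensity units
#'   (background ~0.02, nucleus base ~0.25), so thresholding separates nuclei
#'   from background rather than splitting bright chromocenters from dim
#'   nuclei. Pass `NULL` to search the full intensity range.
#' @param max_area_px giant-nucleus cutoff.
#' @param iou_threshold QC training-label IoU threshold.
#' @param qc_seed,entropy_seed stage seeds.
#' @param n_components PCA components.
#' @param entropy_bins entropy histogram bins.
#' @param group_col grouping column for PCA/entropy contrasts.
#' @param smoothing_sigma_px illumination-correction smoother sigma.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), input_dir = NULL,
                            out_dir = NULL,
                            conditions = list("Gamborg+H" = list()),
                            kernel_size_px = 5L, otsu_range = c(0.03, 0.10),
                            min_area_px = 200L, max_area_px = 5000L,
                            iou_threshold = 0.7, qc_seed = 1L,
                            entropy_seed = 1L, n_components = 2L,
                            entropy_bins = 20L, group_col = "day",
                            smoothing_sigma_px = 50) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full chromatin-phenotyping pipeline
#'
#' Executes the stages in order -- image simulation or loading, maximum
#' intensity projection, illumination correction, segmentation, feature
#' extraction, SVM quality control, ratio quantification, PCA and entropy
#' analysis -- and (when `out_dir` is set) writes every tabular artifact as a
#' CSV stamped with the producing stage and a hash of the configuration.
#' Re-running with an identical configuration reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param stages which stages to run (analysis stages can be skipped).
#' @return list with `features` (QC-filtered `NucleusFeatureTable` with
#'   `ratio` column), `features_raw`, `qc` (model + report + CV accuracy),
#'   `pca` (+ per-group ellipses), `entropy` (`EntropyTable`,
#'   `DifferentialEntropyTable`), `masks`, `manifest` and `artifacts`
#'   (paths written).
#' @export
run_pipeline <- function(config,
                         stages = c("ratio", "pca", "entropy")) {
  hash <- config_hash(unclass(config))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  artifacts <- character(0)
  emit <- function(df, name, stage_name) {
    if (is.null(config$out_dir)) return(invisible(NULL))
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- file.path(config$out_dir, paste0(name, ".csv"))
    write_stage_csv(df, p, stage_name, hash)
    artifacts[[length(artifacts) + 1L]] <<- p
  }

  # -- stage 1: images ------------------------------------------------------
  sim <- stage("simulate", {
    if (!is.null(config$sim)) {
      simulate_timecourse(config$sim, out_dir = NULL,
                          conditions = config$conditions)
    } else {
      if (is.null(config$input_dir) || !dir.exists(config$input_dir))
        stop("input_dir does not exist")
      manifest <- utils::read.csv(file.path(config$input_dir, "manifest.csv"))
      flds <- lapply(seq_len(nrow(manifest)), function(i) {
        fld <- read_field_tiffs(manifest$path_stem[i])
        fld$metadata <- as.list(manifest[i, c("experiment", "condition",
                                              "well", "roi", "day")])
        fld
      })
      list(manifest = manifest, fields = flds)
    }
  })

  # -- stage 2: projection --------------------------------------------------
  projected <- stage("project", lapply(sim$fields, function(f)
    max_project(f$stacks, metadata = f$metadata)))

  # -- stage 3: illumination correction ------------------------------------
  corr <- stage("illumination", correct_illumination(projected,
                                                     config$smoothing_sigma_px))

  # -- stage 4: segmentation ------------------------------------------------
  masks <- stage("segment", lapply(corr$fields, function(f)
    segment_nuclei(f, t_range = config$otsu_range,
                   min_area_px = config$min_area_px,
                   kernel_size_px = config$kernel_size_px)))

  # -- stage 5: features -----------------------------------------------------
  registry <- feature_registry()
  pairs <- Map(function(f, m) list(field = f, mask = m), corr$fields, masks)
  features_raw <- stage("features", extract_features_all(pairs, registry))
  emit(features_raw, "features_raw", "features")

  # -- stage 6: QC -----------------------------------------------------------
  qc <- stage("qc", {
    labels <- character(0)
    for (i in seq_along(masks)) {
      lb <- build_training_labels(sim$fields[[i]]$ground_truth, masks[[i]],
                                  config$iou_threshold)
      labels <- c(labels, lb$class)
    }
    model <- suppressWarnings(train_qc(features_raw, labels,
                                       seed = config$qc_seed))
    res <- apply_qc(features_raw, model, config$max_area_px)
    list(model = model, report = res$report, table = res$table,
         labels = labels)
  })
  features <- qc$table
  emit(features, "features_qc", "qc")

  # -- stage 7: ratio --------------------------------------------------------
  if ("ratio" %in% stages) {
    features <- stage("ratio", {
      bgs <- do.call(rbind, lapply(seq_along(masks), function(i) {
        b <- estimate_background(corr$fields[[i]], masks[[i]])
        cbind(as.data.frame(corr$fields[[i]]$metadata),
              data.frame(bg_num = b[["GFP"]], bg_den = b[["RFP"]]))
      }))
      channel_ratio(features, background = bgs)
    })
    emit(features[, c(feature_table_metadata_cols(), "ratio")],
         "ratios", "ratio")
  }

  # -- stage 8: PCA ----------------------------------------------------------
  pca <- NULL
  if ("pca" %in% stages) {
    pca <- stage("pca", {
      m <- prepare_matrix(features, collapse_by = c("well", config$group_col,
                                                    "condition"),
                          registry = registry)
      p <- pca_svd_impute(m, n_components = config$n_components)
      groups <- attr(m, "samples")[[config$group_col]]
      ell <- lapply(split(seq_len(nrow(p$scores)), groups), function(i)
        if (length(i) >= 3) prediction_ellipse(p$scores[i, 1:2, drop = FALSE])
        else NULL)
      list(pca = p, groups = groups, ellipses = ell)
    })
    emit(data.frame(sample = rownames(pca$pca$scores), pca$pca$scores,
                    check.names = FALSE), "pca_scores", "pca")
    emit(data.frame(feature = rownames(pca$pca$loadings), pca$pca$loadings,
                    check.names = FALSE), "pca_loadings", "pca")
  }

  # -- stage 9: entropy ------------------------------------------------------
  entropy <- NULL
  if ("entropy" %in% stages) {
    entropy <- stage("entropy", {
      et <- entropy_table(features, group_col = config$group_col,
                          registry = registry, n_bins = config$entropy_bins,
                          seed = config$entropy_seed)
      grps <- unique(as.character(features[[config$group_col]]))
      de <- if (length(grps) >= 2)
        differential_entropy(et, grps[which.min(as.numeric(grps))],
                             grps[which.max(as.numeric(grps))])
      else NULL
      list(entropy = et, differential = de)
    })
    emit(entropy$entropy, "entropy", "entropy")
    if (!is.null(entropy$differential))
      emit(entropy$differential, "differential_entropy", "entropy")
  }

  list(features = features, features_raw = features_raw, qc = qc,
       pca = pca, entropy = entropy, masks = masks,
       manifest = sim$manifest, fields = corr$fields,
       artifacts = unlist(artifacts), config_hash = hash)
}
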