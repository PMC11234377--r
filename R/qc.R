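# Segmentation quality control: programmatic A/B labelling against ground
# truth, an RBF support vector machine on 7 object features, and the
# giant-nucleus outlier filter.

QC_FEATURES <- c("Morphology_area", "Morphology_circularity",
                 "Morphology_roundness", "Morphology_elongation",
                 "Morphology_convexity", "Intensity_RFP_mean",
                 "Intensity_GFP_mean")

#' Label segmented objects against ground truth
#'
#' Replaces interactive annotation with programmatic labels: a segmented
#' object is class A (correctly segmented) iff it is the one-to-one best
#' match of a ground-truth nucleus of class "good" with intersection-over-
#' union at or above the threshold; every other object is class B.
#'
#' @param ground_truth ground-truth list (`mask` + `params`) from the
#'   simulator.
#' @param mask a `label_mask` from [segment_nuclei()] on the same field.
#' @param iou_threshold minimum IoU for a correct match.
#' @return data frame (label, class, matched_gt, iou, gt_class).
#' @export
build_training_labels <- function(ground_truth, mask, iou_threshold = 0.7) {
  seg <- mask$labels
  gt <- ground_truth$mask
  if (!identical(dim(seg), dim(gt)))
    stop("mismatched field: ground truth and mask dimensions differ")
  n_seg <- max(seg, 0L)
  if (n_seg == 0)
    return(data.frame(label = integer(0), class = character(0),
                      matched_gt = integer(0), iou = numeric(0),
                      gt_class = character(0)))
  both <- seg > 0 | gt > 0
  tab <- table(seg = seg[both], gt = gt[both])
  seg_area <- tabulate(seg[seg > 0], nbins = n_seg)
  gt_area <- tabulate(gt[gt > 0], nbins = max(gt, 1L))
  # candidate pairs with their IoU
  cand <- which(tab > 0, arr.ind = TRUE)
  s_ids <- as.integer(rownames(tab))[cand[, 1]]
  g_ids <- as.integer(colnames(tab))[cand[, 2]]
  keep <- s_ids > 0 & g_ids > 0
  s_ids <- s_ids[keep]; g_ids <- g_ids[keep]
  inter <- tab[cand][keep]
  iou <- inter / (seg_area[s_ids] + gt_area[g_ids] - inter)
  # greedy one-to-one matching by decreasing IoU
  ord <- order(-iou)
  used_s <- logical(n_seg); used_g <- logical(max(gt, 1L))
  match_gt <- rep(NA_integer_, n_seg)
  match_iou <- rep(0, n_seg)
  for (k in ord) {
    s <- s_ids[k]; g <- g_ids[k]
    if (used_s[s] || used_g[g]) next
    used_s[s] <- TRUE; used_g[g] <- TRUE
    match_gt[s] <- g
    match_iou[s] <- iou[k]
  }
  gt_class <- ground_truth$params$class[match(match_gt, ground_truth$params$id)]
  cls <- ifelse(!is.na(match_gt) & match_iou >= iou_threshold &
                  gt_class == "good", "A", "B")
  cls[is.na(cls)] <- "B"
  data.frame(label = seq_len(n_seg), class = cls, matched_gt = match_gt,
             iou = match_iou, gt_class = ifelse(is.na(gt_class), "none",
                                                gt_class),
             stringsAsFactors = FALSE)
}

#' Train the segmentation-QC support vector machine
#'
#' Fits an RBF-kernel SVM (C = 1) on the seven QC features -- area,
#' circularity, roundness, elongation, convexity and the two channel mean
#' intensities -- z-scored with the training statistics.
#'
#' @param table a `NucleusFeatureTable` containing the QC feature columns.
#' @param labels character vector of classes ("A"/"B"), one per row of
#'   `table`.
#' @param seed integer seed fixing any stochastic solver component.
#' @return an object of class `qc_model`.
#' @export
train_qc <- function(table, labels, seed = 1L) {
  labels <- factor(labels, levels = c("A", "B"))
  if (nlevels(droplevels(labels)) < 2)
    stop("training set must contain both classes")
  if (any(tabulate(labels) < 2))
    stop("need at least 2 objects per class")
  if (any(tabulate(labels) < 40))
    warning("fewer than 40 objects in a class; QC model may be unstable")
  x <- as.matrix(table[, QC_FEATURES, drop = FALSE])
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  fit <- with_seed(seed, e1071::svm(xs, labels, kernel = "radial", cost = 1,
                                    scale = FALSE))
  structure(list(fit = fit, features = QC_FEATURES, center = ctr,
                 scale = scl, seed = seed,
                 n_per_class = table(labels)),
            class = "qc_model")
}

#' @export
print.qc_model <- function(x, ...) {
  cat("Segmentation-QC SVM (RBF, C = 1)\n")
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  cat(sprintf("  training n: A = %d, B = %d\n", x$n_per_class[["A"]],
              x$n_per_class[["B"]]))
  invisible(x)
}

#' @export
predict.qc_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  xs <- scale(x, center = object$center, scale = object$scale)
  as.character(predict(object$fit, xs))
}

#' Save / load a QC model
#'
#' The serialized file embeds the feature order and standardisation
#' constants; predictions are identical after a round trip.
#' @param model a `qc_model`.
#' @param path file path.
#' @export
save_qc_model <- function(model, path) { saveRDS(model, path); invisible(path) }

#' @rdname save_qc_model
#' @export
load_qc_model <- function(path) readRDS(path)

#' Apply QC filtering to a feature table
#'
#' Drops objects the SVM predicts as class B (mis-segmented), then drops
#' giant-nucleus outliers with area strictly greater than `max_area_px`.
#'
#' @param table a `NucleusFeatureTable`.
#' @param model a `qc_model`.
#' @param max_area_px giant-nucleus area cutoff (strict `>`).
#' @return list with `table` (filtered) and `report` (counts per rejection
#'   reason; JSON-serialisable).
#' @export
apply_qc <- function(table, model, max_area_px = 5000L) {
  miss <- setdiff(model$features, colnames(table))
  if (length(miss)) stop("missing QC columns: ", paste(miss, collapse = ", "))
  pred <- predict(model, table)
  keep_svm <- pred == "A"
  giant <- table$Morphology_area > max_area_px
  keep <- keep_svm & !giant
  report <- list(
    n_input = nrow(table),
    n_rejected_svm = sum(!keep_svm),
    n_rejected_giant = sum(keep_svm & giant),
    n_kept = sum(keep)
  )
  list(table = table[keep, , drop = FALSE], report = report)
}

#' k-fold cross-validated accuracy of the QC classifier
#'
#' @param table feature table with QC columns.
#' @param labels class labels parallel to `table`.
#' @param k number of folds.
#' @param seed seed for the fold assignment.
#' @return list with `accuracy` (mean over folds) and `fold_accuracy`.
#' @export
cv_qc <- function(table, labels, k = 5L, seed = 1L) {
  n <- nrow(table)
  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  acc <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    m <- train_qc(table[tr, , drop = FALSE], labels[tr], seed = seed)
    mean(predict(m, table[!tr, , drop = FALSE]) == labels[!tr])
  }, numeric(1))
  list(accuracy = mean(acc), fold_accuracy = acc)
}
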