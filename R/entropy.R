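# Shannon entropy (H0) of single-nucleus feature distributions, differential
# entropy (dH0) between groups, and family-level comparisons. H0 is the
# discretised Shannon entropy in bits: when every nucleus expresses the same
# value for a feature the entropy is zero; the more cell-to-cell variability,
# the higher the entropy.

#' Entropy of one feature across groups
#'
#' Discretises the pooled finite values of all compared groups into
#' `n_bins` equal-width bins (shared bin edges), optionally subsamples every
#' group to the smallest group size (seeded), and computes
#' H0 = -sum p_i log2 p_i over occupied bins, per group.
#'
#' @param values_by_group named list of numeric vectors, one per group.
#' @param n_bins number of equal-width bins over the pooled range.
#' @param subsample_equal_n subsample every group to the smallest group's n.
#' @param seed seed for the subsampling draw.
#' @param min_n groups with fewer finite values are flagged (H0 still
#'   reported).
#' @param feature,family annotations copied into the output rows.
#' @param bias_correction apply the Miller-Madow correction
#'   (K-1)/(2 n ln 2)? Off by default.
#' @return data frame rows (feature, family, group, H0, n, n_bins, bin_min,
#'   bin_max, flag).
#' @export
feature_entropy <- function(values_by_group, n_bins = 20L,
                            subsample_equal_n = TRUE, seed = 1L,
                            min_n = 30L, feature = "feature",
                            family = NA_character_,
                            bias_correction = FALSE) {
  stopifnot(is.list(values_by_group), !is.null(names(values_by_group)))
  vals <- lapply(values_by_group, function(v) v[is.finite(v)])
  pooled <- unlist(vals, use.names = FALSE)
  if (!length(pooled)) stop("all values missing")
  rng <- range(pooled)
  edges <- if (rng[1] == rng[2]) c(rng[1] - 0.5, rng[1] + 0.5)
           else seq(rng[1], rng[2], length.out = n_bins + 1L)
  if (subsample_equal_n) {
    n_min <- min(lengths(vals))
    vals <- lapply(seq_along(vals), function(i) {
      v <- vals[[i]]
      if (length(v) > n_min)
        v[with_seed(derive_seed(seed, feature, names(values_by_group)[i]),
                    sample(length(v), n_min))]
      else v
    })
    names(vals) <- names(values_by_group)
  }
  rows <- lapply(names(vals), function(g) {
    v <- vals[[g]]
    if (!length(v))
      return(data.frame(feature = feature, family = family, group = g,
                        H0 = NA_real_, n = 0L, n_bins = n_bins,
                        bin_min = rng[1], bin_max = rng[2],
                        flag = "no finite values", stringsAsFactors = FALSE))
    b <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
    p <- tabulate(b, nbins = length(edges) - 1L) / length(v)
    p <- p[p > 0]
    h <- -sum(p * log2(p))
    if (bias_correction) h <- h + (length(p) - 1) / (2 * length(v) * log(2))
    data.frame(feature = feature, family = family, group = g, H0 = h,
               n = length(v), n_bins = n_bins, bin_min = rng[1],
               bin_max = rng[2],
               flag = if (length(v) < min_n) "n below min_n" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Entropy table over many features of a nucleus feature table
#'
#' Applies [feature_entropy()] to each feature column, grouping nuclei by
#' `group_col` (nuclei are pooled across replicate wells within each group by
#' default).
#'
#' @param table a `NucleusFeatureTable`.
#' @param features feature columns to analyse; defaults to all
#'   analysis-eligible registry features present.
#' @param group_col metadata column defining the compared groups (e.g.
#'   `"day"`).
#' @param registry the [feature_registry()] used for family annotation.
#' @inheritParams feature_entropy
#' @return an `EntropyTable` data frame.
#' @export
entropy_table <- function(table, features = NULL, group_col = "day",
                          registry = feature_registry(), n_bins = 20L,
                          subsample_equal_n = TRUE, seed = 1L, min_n = 30L,
                          bias_correction = FALSE) {
  if (is.null(features))
    features <- intersect(registry$name[registry$analysis_eligible],
                          colnames(table))
  # features never measured (e.g. methods subset at extraction) are skipped
  measured <- vapply(features, function(f) any(is.finite(table[[f]])),
                     logical(1))
  features <- features[measured]
  grp <- as.character(table[[group_col]])
  fam <- registry$family[match(features, registry$name)]
  out <- lapply(seq_along(features), function(i) {
    feature_entropy(split(table[[features[i]]], grp), n_bins = n_bins,
                    subsample_equal_n = subsample_equal_n, seed = seed,
                    min_n = min_n, feature = features[i], family = fam[i],
                    bias_correction = bias_correction)
  })
  do.call(rbind, out)
}

#' Differential entropy between two groups
#'
#' dH0 = H0(group1) - H0(group0) per feature; features missing either group
#' are excluded (count reported as an attribute).
#'
#' @param etab an [entropy_table()] output.
#' @param group0,group1 group labels (e.g. day 0 and day 5).
#' @return a `DifferentialEntropyTable` data frame (feature, family, dH0,
#'   H0_group0, H0_group1) with attribute `n_excluded`.
#' @export
differential_entropy <- function(etab, group0, group1) {
  e0 <- etab[etab$group == as.character(group0) & !is.na(etab$H0), ]
  e1 <- etab[etab$group == as.character(group1) & !is.na(etab$H0), ]
  feats <- intersect(e0$feature, e1$feature)
  n_excl <- length(union(e0$feature, e1$feature)) - length(feats)
  if (!length(feats)) {
    warning("disjoint feature sets between groups")
    out <- data.frame(feature = character(0), family = character(0),
                      dH0 = numeric(0), H0_group0 = numeric(0),
                      H0_group1 = numeric(0))
    attr(out, "n_excluded") <- n_excl
    return(out)
  }
  i0 <- match(feats, e0$feature); i1 <- match(feats, e1$feature)
  out <- data.frame(feature = feats, family = e0$family[i0],
                    dH0 = e1$H0[i1] - e0$H0[i0],
                    H0_group0 = e0$H0[i0], H0_group1 = e1$H0[i1],
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n_excl
  out
}

#' Compare differential entropies over the features of one family
#'
#' With two differential-entropy tables, runs a paired Wilcoxon signed-rank
#' test of dH0 across the features matched one-to-one between the two
#' conditions. With a single table, tests the condition's dH0 against zero
#' (one-sample signed-rank).
#'
#' @param delta_a a [differential_entropy()] table (condition A).
#' @param delta_b optional second table (condition B) for the two-condition
#'   contrast.
#' @param family restrict to one feature family (e.g. "texture"); `NULL`
#'   uses all features.
#' @param min_features minimum number of matched features required.
#' @return a `group_comparison` object.
#' @export
family_entropy_comparison <- function(delta_a, delta_b = NULL, family = NULL,
                                      min_features = 5L) {
  pick <- function(d) if (is.null(family)) d else d[d$family %in% family, ]
  a <- pick(delta_a)
  if (is.null(delta_b)) {
    if (nrow(a) < min_features)
      stop("fewer than ", min_features, " matched features")
    ht <- signed_rank_test(a$dH0)
    return(structure(list(test = "Wilcoxon signed-rank (dH0 vs 0)",
                          groups = "A", n = nrow(a),
                          statistic = ht$statistic, p_value = ht$p_value,
                          median_dH0 = stats::median(a$dH0)),
                     class = "group_comparison"))
  }
  b <- pick(delta_b)
  feats <- intersect(a$feature, b$feature)
  if (length(feats) < min_features)
    stop("fewer than ", min_features, " matched features")
  va <- a$dH0[match(feats, a$feature)]
  vb <- b$dH0[match(feats, b$feature)]
  ht <- signed_rank_test(va - vb)
  structure(list(test = "paired Wilcoxon signed-rank (dH0 A vs B)",
                 groups = c("A", "B"), n = c(length(va), length(vb)),
                 statistic = ht$statistic, p_value = ht$p_value,
                 median_dH0 = c(A = stats::median(va), B = stats::median(vb))),
            class = "group_comparison")
}
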