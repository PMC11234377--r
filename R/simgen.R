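# Synthetic two-channel nucleus image simulator with ground truth.
#
# The simulator emulates the statistical structure the downstream analysis
# assumes: elliptical nuclei carrying chromocenter-like Gaussian intensity
# blobs in a "total chromatin" (RFP) channel, a co-localised "linker histone"
# (GFP) channel equal to the RFP pattern times a per-nucleus ratio, a
# day-dependent decline of that ratio, day-dependent population heterogeneity,
# mis-segmentation distractors (border-truncated, merged pairs, debris),
# a smooth multiplicative illumination bias shared by all fields of an
# experiment, a Gaussian focal profile across z-planes, and Poisson + Gaussian
# pixel noise.

#' Simulation configuration
#'
#' Builds and validates the configuration driving the synthetic time-course
#' generator. Per-day schedules (`ratio_mean`, `ratio_cv`,
#' `heterogeneity_scale`, `chromocenter_contrast`) may be given as a single
#' value (recycled) or one value per entry of `days`.
#'
#' @param field_size_px integer (height, width) of a field, each >= 64.
#' @param n_zplanes number of z-planes per stack.
#' @param pixel_size_um pixel pitch in micrometres.
#' @param n_fields_per_well imaged regions of interest per well.
#' @param n_wells replicate culture wells per condition.
#' @param days strictly increasing integer sampling days.
#' @param nuclei_per_field_mean Poisson mean of well-formed nuclei per field.
#' @param nucleus_axis_log_mean,nucleus_axis_log_sd log-normal parameters of
#'   the nucleus semi-major axis in pixels.
#' @param chromocenter_count_range integer interval for chromocenters per
#'   nucleus.
#' @param chromocenter_contrast per-day mean contrast of chromocenter blobs
#'   relative to the nucleus base intensity (>= 0).
#' @param ratio_mean,ratio_cv per-day mean and coefficient of variation of the
#'   GFP:RFP intensity ratio (truncated at 0).
#' @param heterogeneity_scale per-day multiplier (>= 0) applied to the
#'   population SDs of shape/texture parameters; 0 makes all nuclei of a field
#'   share identical shape and texture parameters.
#' @param distractor_rates named Poisson rates per field for the three
#'   mis-segmentation classes `truncated`, `merged`, `debris`.
#' @param bias_field_amplitude amplitude (>= 0) of the multiplicative
#'   illumination bias shared across fields.
#' @param noise list with `poisson_gain` (photons per intensity unit; 0
#'   disables shot noise) and `gaussian_sd` (additive read noise).
#' @param background uniform background intensity level.
#' @param base_intensity_mean mean in-focus nucleus intensity (RFP channel).
#' @param seed integer master seed; identical config + seed gives identical
#'   output.
#' @param experiment experiment label written into metadata.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(field_size_px = c(512L, 512L),
                       n_zplanes = 8L,
                       pixel_size_um = 0.108,
                       n_fields_per_well = 2L,
                       n_wells = 4L,
                       days = c(0L, 2L, 5L),
                       nuclei_per_field_mean = 30,
                       nucleus_axis_log_mean = log(14),
                       nucleus_axis_log_sd = 0.18,
                       chromocenter_count_range = c(4L, 10L),
                       chromocenter_contrast = c(0.6, 1.0, 1.4),
                       ratio_mean = c(1.0, 0.55, 0.3),
                       ratio_cv = 0.2,
                       heterogeneity_scale = c(1.0, 0.75, 0.5),
                       distractor_rates = c(truncated = 2, merged = 1, debris = 2),
                       bias_field_amplitude = 0.15,
                       noise = list(poisson_gain = 200, gaussian_sd = 0.01),
                       background = 0.02,
                       base_intensity_mean = 0.25,
                       seed = 1L,
                       experiment = "SIM001") {
  nd <- length(days)
  rec <- function(x, what) {
    if (length(x) == 1L) x <- rep(x, nd)
    if (length(x) != nd)
      stop(sprintf("'%s' must have length 1 or length(days)", what))
    stats::setNames(x, as.character(days))
  }
  cfg <- list(
    field_size_px = as.integer(field_size_px),
    n_zplanes = as.integer(n_zplanes),
    pixel_size_um = pixel_size_um,
    n_fields_per_well = as.integer(n_fields_per_well),
    n_wells = as.integer(n_wells),
    days = as.integer(days),
    nuclei_per_field_mean = nuclei_per_field_mean,
    nucleus_axis_log_mean = nucleus_axis_log_mean,
    nucleus_axis_log_sd = nucleus_axis_log_sd,
    chromocenter_count_range = as.integer(chromocenter_count_range),
    chromocenter_contrast = rec(chromocenter_contrast, "chromocenter_contrast"),
    ratio_mean = rec(ratio_mean, "ratio_mean"),
    ratio_cv = rec(ratio_cv, "ratio_cv"),
    heterogeneity_scale = rec(heterogeneity_scale, "heterogeneity_scale"),
    distractor_rates = distractor_rates,
    bias_field_amplitude = bias_field_amplitude,
    noise = noise,
    background = background,
    base_intensity_mean = base_intensity_mean,
    seed = as.integer(seed),
    experiment = experiment
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (length(cfg$field_size_px) != 2L || any(cfg$field_size_px < 64L))
    stop("field dimensions must be two integers >= 64")
  if (cfg$n_zplanes < 1L) stop("n_zplanes must be >= 1")
  if (cfg$pixel_size_um <= 0) stop("pixel_size_um must be positive")
  if (length(cfg$days) < 1L || any(diff(cfg$days) <= 0))
    stop("days must be strictly increasing")
  if (cfg$nuclei_per_field_mean < 0) stop("nuclei_per_field_mean must be >= 0")
  if (cfg$nucleus_axis_log_sd < 0) stop("nucleus_axis_log_sd must be >= 0")
  if (any(cfg$chromocenter_contrast < 0) || any(cfg$ratio_cv < 0) ||
      any(cfg$heterogeneity_scale < 0))
    stop("all rates and SDs must be >= 0")
  if (is.null(names(cfg$distractor_rates)) ||
      !all(c("truncated", "merged", "debris") %in% names(cfg$distractor_rates)))
    stop("distractor_rates must name truncated, merged and debris")
  if (any(cfg$distractor_rates < 0)) stop("distractor rates must be >= 0")
  if (cfg$bias_field_amplitude < 0) stop("bias_field_amplitude must be >= 0")
  if (cfg$noise$poisson_gain < 0 || cfg$noise$gaussian_sd < 0)
    stop("noise parameters must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic chromatin time-course configuration\n")
  cat(sprintf("  field: %d x %d px, %d z-planes, %.3f um/px\n",
              x$field_size_px[1], x$field_size_px[2], x$n_zplanes,
              x$pixel_size_um))
  cat(sprintf("  layout: %d wells x %d fields, days {%s}\n", x$n_wells,
              x$n_fields_per_well, paste(x$days, collapse = ", ")))
  cat(sprintf("  nuclei/field ~ Pois(%.1f); ratio schedule: %s\n",
              x$nuclei_per_field_mean,
              paste(sprintf("%g", x$ratio_mean), collapse = " -> ")))
  cat(sprintf("  heterogeneity schedule: %s; seed %d\n",
              paste(sprintf("%g", x$heterogeneity_scale), collapse = " -> "),
              x$seed))
  invisible(x)
}

# non-overlapping centre placement by rejection sampling
place_objects <- function(n, radii, lo_r, hi_r, lo_c, hi_c, existing = NULL,
                          max_tries = 2000L) {
  pts <- existing %||% matrix(numeric(0), ncol = 3)  # cy, cx, rad
  out <- matrix(NA_real_, n, 2)
  kept <- logical(n)
  for (i in seq_len(n)) {
    for (try in seq_len(max_tries)) {
      cy <- stats::runif(1, lo_r[i], hi_r[i])
      cx <- stats::runif(1, lo_c[i], hi_c[i])
      ok <- TRUE
      if (nrow(pts)) {
        d <- sqrt((pts[, 1] - cy)^2 + (pts[, 2] - cx)^2)
        ok <- all(d > (pts[, 3] + radii[i]) * 1.05 + 4)
      }
      if (ok) {
        pts <- rbind(pts, c(cy, cx, radii[i]))
        out[i, ] <- c(cy, cx)
        kept[i] <- TRUE
        break
      }
    }
  }
  list(centres = out, kept = kept, pts = pts)
}

#' Sample the per-nucleus population of one field
#'
#' Draws the ground-truth parameter table for a single field at a given day:
#' a Poisson number of well-formed nuclei plus Poisson numbers of
#' border-truncated, merged-pair and debris distractors, with all shape and
#' texture dispersions scaled by the day's `heterogeneity_scale` and GFP:RFP
#' ratios drawn from the day's ratio distribution truncated at zero.
#'
#' @param config a [sim_config()].
#' @param day one of `config$days`.
#' @param seed integer seed for this field's stream.
#' @return data frame with one row per ground-truth object (class
#'   good/truncated/merged/debris); merged objects carry second-lobe
#'   parameters in `a2`, `b2`, `cy2`, `cx2`.
#' @export
sample_population <- function(config, day, seed = derive_seed(config$seed, day)) {
  if (!day %in% config$days)
    stop(sprintf("unknown day %s: not in config$days", format(day)))
  d <- as.character(day)
  h <- config$heterogeneity_scale[[d]]
  nr <- config$field_size_px[1]; nc <- config$field_size_px[2]

  with_seed(seed, {
    n_good <- stats::rpois(1, config$nuclei_per_field_mean)
    n_trunc <- stats::rpois(1, config$distractor_rates[["truncated"]])
    n_merge <- stats::rpois(1, config$distractor_rates[["merged"]])
    n_debris <- stats::rpois(1, config$distractor_rates[["debris"]])
    n_all <- n_good + n_trunc + n_merge + n_debris
    cls <- rep(c("good", "truncated", "merged", "debris"),
               c(n_good, n_trunc, n_merge, n_debris))

    draw_shape <- function(n) {
      a <- exp(stats::rnorm(n, config$nucleus_axis_log_mean,
                            config$nucleus_axis_log_sd * h))
      ratio_ab <- pmin(1, pmax(0.45, 0.75 + stats::rnorm(n, 0, 0.12 * h)))
      list(a = a, b = a * ratio_ab)
    }
    sh <- draw_shape(n_all)
    a <- sh$a; b <- sh$b
    theta <- stats::runif(n_all, 0, pi)
    base_int <- config$base_intensity_mean *
      exp(stats::rnorm(n_all, 0, 0.15 * h))
    ratio <- pmax(0, stats::rnorm(n_all, config$ratio_mean[[d]],
                                  config$ratio_mean[[d]] * config$ratio_cv[[d]]))
    ccr <- config$chromocenter_count_range
    mid <- mean(ccr)
    n_chromo <- as.integer(round(mid + (stats::runif(n_all) - 0.5) *
                                   diff(ccr) * min(h, 1)))
    contrast <- pmax(0, config$chromocenter_contrast[[d]] +
                       stats::rnorm(n_all, 0, 0.35 * h))
    z0 <- stats::runif(n_all, 1.5, max(1.5, config$n_zplanes - 0.5))

    # debris: dim, elongated, texture-free objects above the size filter
    is_deb <- cls == "debris"
    if (any(is_deb)) {
      a[is_deb] <- stats::runif(sum(is_deb), 15, 20)
      b[is_deb] <- a[is_deb] * stats::runif(sum(is_deb), 0.28, 0.40)
      base_int[is_deb] <- stats::runif(sum(is_deb), 0.13, 0.18)
      ratio[is_deb] <- stats::runif(sum(is_deb), 0.02, 0.10)
      n_chromo[is_deb] <- 0L
      contrast[is_deb] <- 0
    }

    # placement: interior objects keep their whole ellipse inside the field
    margin <- a + 4
    lo_r <- 1 + margin; hi_r <- nr - margin
    lo_c <- 1 + margin; hi_c <- nc - margin
    is_tr <- cls == "truncated"
    if (any(is_tr)) {
      # centre within half an axis of a randomly chosen edge
      for (i in which(is_tr)) {
        edge <- sample(4L, 1L)
        off <- stats::runif(1, -a[i] / 2, a[i] / 2)
        if (edge == 1L) { lo_r[i] <- hi_r[i] <- 1 + off }
        if (edge == 2L) { lo_r[i] <- hi_r[i] <- nr - off }
        if (edge == 3L) { lo_c[i] <- hi_c[i] <- 1 + off }
        if (edge == 4L) { lo_c[i] <- hi_c[i] <- nc - off }
      }
      lo_r[is_tr & lo_r > hi_r] <- hi_r[is_tr & lo_r > hi_r]  # degenerate guard
    }
    # merged pairs reserve room for their second lobe
    radii_eff <- ifelse(cls == "merged", 2.2 * a, a)
    pl <- place_objects(n_all, radii = radii_eff, lo_r = pmin(lo_r, hi_r),
                        hi_r = pmax(lo_r, hi_r), lo_c = pmin(lo_c, hi_c),
                        hi_c = pmax(lo_c, hi_c))
    keep <- pl$kept
    pars <- data.frame(
      id = seq_len(sum(keep)),
      class = cls[keep],
      cy = pl$centres[keep, 1], cx = pl$centres[keep, 2],
      a = a[keep], b = b[keep], theta = theta[keep],
      base_int = base_int[keep], ratio = ratio[keep],
      n_chromo = n_chromo[keep], chromo_contrast = contrast[keep],
      z0 = z0[keep],
      cy2 = rep(NA_real_, sum(keep)), cx2 = rep(NA_real_, sum(keep)),
      a2 = rep(NA_real_, sum(keep)), b2 = rep(NA_real_, sum(keep)),
      theta2 = rep(NA_real_, sum(keep)),
      stringsAsFactors = FALSE
    )
    # second lobe of merged pairs, overlapping the first
    im <- which(pars$class == "merged")
    if (length(im)) {
      sh2 <- draw_shape(length(im))
      ang <- stats::runif(length(im), 0, 2 * pi)
      dist <- 0.85 * (pars$a[im] + sh2$a) / 2 + 2
      pars$a2[im] <- sh2$a; pars$b2[im] <- sh2$b
      pars$theta2[im] <- stats::runif(length(im), 0, pi)
      pars$cy2[im] <- pmin(pmax(pars$cy[im] + dist * sin(ang), sh2$a + 2),
                           nr - sh2$a - 2)
      pars$cx2[im] <- pmin(pmax(pars$cx[im] + dist * cos(ang), sh2$a + 2),
                           nc - sh2$a - 2)
    }
    pars
  })
}

# smooth fixed illumination bias, mean ~1, shared across an experiment
bias_field <- function(dim_hw, amplitude, seed) {
  if (amplitude <= 0) return(matrix(1, dim_hw[1], dim_hw[2]))
  with_seed(seed, {
    ph <- stats::runif(4, 0, 2 * pi)
    fr <- stats::runif(2, 0.6, 1.4)
    y <- seq(-1, 1, length.out = dim_hw[1])
    x <- seq(-1, 1, length.out = dim_hw[2])
    g <- outer(cos(fr[1] * pi * y + ph[1]), cos(fr[2] * pi * x + ph[2])) +
      0.5 * outer(sin(0.7 * pi * y + ph[3]), rep(1, dim_hw[2])) +
      0.5 * matrix(sin(0.7 * pi * x + ph[4]), dim_hw[1], dim_hw[2], byrow = TRUE)
    g <- g - mean(g)
    1 + amplitude * g / max(abs(g))
  })
}

# add one elliptical lobe (flat base + chromocenter blobs) into patch stores
render_lobe <- function(img, cy, cx, a, b, theta, intensity, n_chromo,
                        contrast, sigma_c = 2.5, chromo_seed = NULL) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- max(1L, floor(cy - a - 3 * sigma_c)); r1 <- min(nr, ceiling(cy + a + 3 * sigma_c))
  c0 <- max(1L, floor(cx - a - 3 * sigma_c)); c1 <- min(nc, ceiling(cx + a + 3 * sigma_c))
  if (r0 > r1 || c0 > c1) return(img)
  rr <- r0:r1; cc <- c0:c1
  dy <- matrix(rr - cy, length(rr), length(cc))
  dx <- matrix(cc - cx, length(rr), length(cc), byrow = TRUE)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- (u^2 + v^2) <= 1
  patch <- matrix(0, length(rr), length(cc))
  patch[inside] <- intensity
  if (n_chromo > 0 && contrast > 0) {
    # chromocenter centres drawn inside the 0.65-scaled ellipse
    k <- 0L; tries <- 0L
    while (k < n_chromo && tries < 50L * n_chromo) {
      tries <- tries + 1L
      pu <- stats::runif(1, -0.65, 0.65); pv <- stats::runif(1, -0.65, 0.65)
      if (pu^2 / 0.65^2 + pv^2 / 0.65^2 > 1) next
      k <- k + 1L
      py <- cy + a * pu * sin(theta) + b * pv * cos(theta)
      px <- cx + a * pu * cos(theta) - b * pv * sin(theta)
      blob <- contrast * intensity *
        exp(-((matrix(rr - py, length(rr), length(cc)))^2 +
                (matrix(cc - px, length(rr), length(cc), byrow = TRUE))^2) /
              (2 * sigma_c^2))
      patch[inside] <- patch[inside] + blob[inside]
    }
  }
  img[rr, cc] <- img[rr, cc] + patch
  img
}

lobe_mask <- function(nr, nc, cy, cx, a, b, theta) {
  r0 <- max(1L, floor(cy - a)); r1 <- min(nr, ceiling(cy + a))
  c0 <- max(1L, floor(cx - a)); c1 <- min(nc, ceiling(cx + a))
  out <- matrix(FALSE, nr, nc)
  if (r0 > r1 || c0 > c1) return(out)
  rr <- r0:r1; cc <- c0:c1
  dy <- matrix(rr - cy, length(rr), length(cc))
  dx <- matrix(cc - cx, length(rr), length(cc), byrow = TRUE)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  out[rr, cc] <- (u^2 + v^2) <= 1
  out
}

#' Render one two-channel z-stack field with ground truth
#'
#' Composites the per-nucleus ideal images (flat elliptical base plus
#' chromocenter blobs), weights them across z-planes with a per-nucleus
#' Gaussian focal profile normalised to peak 1 (so a maximum-intensity
#' projection of the noiseless stack recovers the in-focus image), applies the
#' experiment's multiplicative bias field, and adds Poisson shot noise and
#' Gaussian read noise per plane. The GFP channel is the RFP spatial pattern
#' scaled by each nucleus's ratio, with its own independent noise.
#'
#' @param params parameter table from [sample_population()].
#' @param config a [sim_config()].
#' @param seed integer seed for the rendering stream.
#' @param bias optional precomputed bias field (defaults to the experiment's).
#' @return list with `stacks` (named list RFP/GFP of h x w x z arrays) and
#'   `ground_truth` (list with integer `mask` and the `params` table).
#' @export
render_field <- function(params, config, seed = derive_seed(config$seed, "render"),
                         bias = NULL) {
  nr <- config$field_size_px[1]; nc <- config$field_size_px[2]
  if (nr < 1 || nc < 1) stop("zero-size field")
  if (config$noise$poisson_gain < 0 || config$noise$gaussian_sd < 0)
    stop("negative noise parameters")
  nz <- config$n_zplanes
  if (is.null(bias))
    bias <- bias_field(c(nr, nc), config$bias_field_amplitude,
                       derive_seed(config$seed, "bias"))

  with_seed(seed, {
    # ideal in-focus images composed per nucleus so that the focal profile can
    # differ between nuclei
    ideal_rfp <- vector("list", nrow(params))
    mask <- matrix(0L, nr, nc)
    for (i in seq_len(nrow(params))) {
      p <- params[i, ]
      img <- matrix(0, nr, nc)
      img <- render_lobe(img, p$cy, p$cx, p$a, p$b, p$theta, p$base_int,
                         p$n_chromo, p$chromo_contrast)
      m <- lobe_mask(nr, nc, p$cy, p$cx, p$a, p$b, p$theta)
      if (p$class == "merged" && !is.na(p$a2)) {
        img <- render_lobe(img, p$cy2, p$cx2, p$a2, p$b2, p$theta2, p$base_int,
                           p$n_chromo, p$chromo_contrast)
        m <- m | lobe_mask(nr, nc, p$cy2, p$cx2, p$a2, p$b2, p$theta2)
      }
      ideal_rfp[[i]] <- img
      mask[m] <- p$id
    }

    stacks <- list(
      RFP = array(0, c(nr, nc, nz)),
      GFP = array(0, c(nr, nc, nz))
    )
    zw <- function(z0) {
      w <- exp(-((1:nz) - z0)^2 / (2 * 1.2^2))
      w / max(w)
    }
    wmat <- vapply(params$z0, zw, numeric(nz))  # nz x n_obj
    for (z in seq_len(nz)) {
      sig_r <- matrix(0, nr, nc); sig_g <- matrix(0, nr, nc)
      for (i in seq_len(nrow(params))) {
        w <- if (nrow(params)) wmat[z, i] else 0
        if (w < 1e-4) next
        sig_r <- sig_r + w * ideal_rfp[[i]]
        sig_g <- sig_g + w * params$ratio[i] * ideal_rfp[[i]]
      }
      for (ch in c("RFP", "GFP")) {
        x <- bias * (config$background + if (ch == "RFP") sig_r else sig_g)
        if (config$noise$poisson_gain > 0)
          x <- stats::rpois(length(x), pmax(x, 0) * config$noise$poisson_gain) /
            config$noise$poisson_gain
        if (config$noise$gaussian_sd > 0)
          x <- x + stats::rnorm(length(x), 0, config$noise$gaussian_sd)
        stacks[[ch]][, , z] <- pmax(matrix(x, nr, nc), 0)
      }
    }
    list(stacks = stacks,
         ground_truth = list(mask = mask, params = params))
  })
}

#' Simulate a full time-course experiment
#'
#' Generates one two-channel image set per condition x well x field x day.
#' With `out_dir = NULL` everything stays in memory; otherwise per-channel
#' multi-page 16-bit TIFF stacks, ground-truth label masks, per-field
#' parameter CSVs, a manifest CSV and the configuration JSON are written under
#' `out_dir`.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory or `NULL` for in-memory output.
#' @param conditions named list of per-condition configuration overrides; the
#'   names become the `condition` labels in the manifest.
#' @return invisibly, a list with `manifest` (data frame) and `fields` (list of
#'   rendered fields, in manifest order; with `out_dir` set each entry also
#'   records its file paths).
#' @export
simulate_timecourse <- function(config, out_dir = NULL,
                                conditions = list("Gamborg+H" = list())) {
  if (!is.null(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("unwritable output path: ", out_dir)
  }
  manifest <- NULL
  fields <- list()
  for (cond in names(conditions)) {
    ccfg <- config
    for (nm in names(conditions[[cond]])) ccfg[[nm]] <- conditions[[cond]][[nm]]
    ccfg <- validate_sim_config(unclass(ccfg))
    bias <- bias_field(ccfg$field_size_px, ccfg$bias_field_amplitude,
                       derive_seed(config$seed, "bias", cond))
    for (w in seq_len(ccfg$n_wells)) {
      well <- sprintf("W%02d", w)
      for (day in ccfg$days) {
        for (f in seq_len(ccfg$n_fields_per_well)) {
          sp_seed <- derive_seed(config$seed, cond, well, day, f, "pop")
          rf_seed <- derive_seed(config$seed, cond, well, day, f, "render")
          pars <- sample_population(structure(ccfg, class = "sim_config"),
                                    day, seed = sp_seed)
          fld <- render_field(pars, ccfg, seed = rf_seed, bias = bias)
          meta <- data.frame(experiment = config$experiment, condition = cond,
                             well = well, roi = f, day = day,
                             stringsAsFactors = FALSE)
          fld$metadata <- as.list(meta)
          if (!is.null(out_dir)) {
            stem <- file.path(out_dir, sprintf("%s_%s_d%02d_f%02d",
                                               gsub("[^A-Za-z0-9+-]", "-", cond),
                                               well, day, f))
            fld$paths <- write_field_tiffs(fld, stem)
            meta$path_stem <- stem
          }
          manifest <- rbind(manifest, meta)
          fields[[length(fields) + 1L]] <- fld
        }
      }
    }
  }
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(manifest = manifest, fields = fields))
}

# 16-bit TIFF output: intensities clipped to [0,1]; label masks stored as
# label/65535 so they survive the 16-bit round trip exactly
write_field_tiffs <- function(field, stem) {
  paths <- c(RFP = paste0(stem, "_RFP.tif"), GFP = paste0(stem, "_GFP.tif"),
             mask = paste0(stem, "_mask.tif"), params = paste0(stem, "_params.csv"))
  for (ch in c("RFP", "GFP")) {
    st <- field$stacks[[ch]]
    pages <- lapply(seq_len(dim(st)[3]), function(z) pmin(st[, , z], 1))
    tiff::writeTIFF(pages, paths[[ch]], bits.per.sample = 16L)
  }
  tiff::writeTIFF(field$ground_truth$mask / 65535, paths[["mask"]],
                  bits.per.sample = 16L)
  utils::write.csv(field$ground_truth$params, paths[["params"]],
                   row.names = FALSE)
  paths
}

#' Read a simulated field back from disk
#'
#' @param stem path stem as recorded in the manifest's `path_stem` column.
#' @return list with `stacks`, `ground_truth` as produced by [render_field()].
#' @export
read_field_tiffs <- function(stem) {
  rd <- function(p) {
    pages <- tiff::readTIFF(p, all = TRUE)
    array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  }
  mask <- round(tiff::readTIFF(paste0(stem, "_mask.tif")) * 65535)
  storage.mode(mask) <- "integer"
  list(stacks = list(RFP = rd(paste0(stem, "_RFP.tif")),
                     GFP = rd(paste0(stem, "_GFP.tif"))),
       ground_truth = list(mask = mask,
                           params = utils::read.csv(paste0(stem, "_params.csv"))))
}
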