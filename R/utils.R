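# Internal helpers: seeded RNG plumbing, convolution, hashing.

#' Derive a reproducible sub-seed from a base seed and a stream label
#'
#' A small multiplicative hash folding the base seed and an arbitrary set of
#' labels (coerced to character) into an integer in [1, 2^31 - 2]. Used so that
#' every field/well/day of a simulation draws from its own stream while the
#' whole experiment stays a pure function of the configuration seed.
#'
#' @param seed integer base seed.
#' @param ... labels (well id, day, field index, ...) identifying the stream.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  labs <- paste(vapply(list(...), function(x) paste(format(x), collapse = "|"),
                       character(1)), collapse = "/")
  h <- as.numeric(seed) %% 2147483647
  for (b in utf8ToInt(labs)) h <- (h * 31 + b) %% 2147483647
  as.integer(h %% 2147483646L + 1L)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded helpers do not perturb the
#' caller's RNG stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Hash an R object to a short hex string
#'
#' FNV-style fold over the serialized bytes; used to stamp output CSVs with the
#' configuration they were produced from.
#' @keywords internal
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  # skip the serialization header (R version dependent)
  bytes <- bytes[-seq_len(14)]
  h <- 2166136261
  for (b in bytes) h <- (h * 16777619 + b) %% 4294967296
  sprintf("%08x", as.integer(h %% 2147483647))
}

#' Truncated, normalized 2-D Gaussian kernel
#' @keywords internal
gaussian_kernel <- function(size, sigma) {
  stopifnot(size >= 1, size %% 2 == 1, sigma > 0)
  half <- (size - 1) / 2
  g1 <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- outer(g1, g1)
  k / sum(k)
}

#' 2-D convolution with replicated (edge-extended) boundary
#' @keywords internal
conv2_replicate <- function(x, kernel) {
  EBImage::filter2(x, kernel, boundary = "replicate")
}

#' Separable Gaussian smoothing with replicated boundary
#'
#' Kernel truncated at 4 sigma. Used for bias-field estimation where sigma is
#' large and the kernel size is not externally prescribed.
#' @keywords internal
smooth_gaussian_wide <- function(x, sigma) {
  if (sigma <= 0) return(x)
  g1 <- function(n) {
    # kernel truncated at 4 sigma, clamped to the image extent
    half <- min(max(1L, as.integer(ceiling(4 * sigma))),
                as.integer((n - 1) %/% 2))
    g <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
    g / sum(g)
  }
  # separable passes via filter2 with 1-D kernels
  x1 <- EBImage::filter2(x, matrix(g1(nrow(x)), ncol = 1),
                         boundary = "replicate")
  EBImage::filter2(x1, matrix(g1(ncol(x)), nrow = 1), boundary = "replicate")
}

#' Write a data frame as CSV with a provenance comment header
#' @param df data frame to write.
#' @param path output path.
#' @param stage name of the producing pipeline stage.
#' @param hash configuration hash stamped into the header.
#' @export
write_stage_csv <- function(df, path, stage, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stage: %s; config_hash: %s", stage, hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_stage_csv()]
#' @param path CSV path.
#' @export
read_stage_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
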