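#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange bind_rows bind_cols group_by
#'   summarise ungroup left_join n across all_of pull slice rename
#' @importFrom stats median mad quantile sd var rnorm runif rpois fft prcomp
#'   kmeans predict glm binomial dist setNames approx
#' @importFrom utils head tail
#' @importFrom grDevices chull
#' @importFrom tools file_ext
NULL

# clamp numeric vector/array into [lo, hi]
clip <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)

# deterministic child seed derivation; stays within 32-bit signed range
derive_seed <- function(seed, index) {
  s <- (as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647
  as.integer(max(1, s))
}

# rounded ITU luminance of an RGB array (H x W x 3, 0..255)
luminance <- function(image) {
  round(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
}

# eight-number summary used for all per-object feature aggregation.
# Empty input and undefined spreads are defined as 0 so downstream tables
# never contain missing values.
agg8 <- function(x, prefix) {
  if (length(x) == 0 || all(!is.finite(x))) {
    v <- rep(0, 8)
  } else {
    x <- x[is.finite(x)]
    v <- c(
      mean(x), median(x),
      if (length(x) > 1) sd(x) else 0,
      mad(x),
      min(x), max(x),
      quantile(x, 0.25, names = FALSE), quantile(x, 0.75, names = FALSE)
    )
  }
  names(v) <- paste0(prefix, "_", c("mean", "median", "sd", "mad", "min", "max", "q1", "q3"))
  v
}

agg8_suffixes <- c("mean", "median", "sd", "mad", "min", "max", "q1", "q3")

# histogram of fractions with fixed uniform bins on [lo, hi); values outside
# are clamped into the edge bins. Returns a vector of length nbins summing to 1
# (or all zeros when x is empty).
fraction_hist <- function(x, lo, hi, nbins) {
  if (length(x) == 0) return(rep(0, nbins))
  idx <- floor((x - lo) / (hi - lo) * nbins) + 1
  idx <- pmin(pmax(idx, 1), nbins)
  tabulate(idx, nbins) / length(x)
}

safe_div <- function(a, b) if (b == 0) 0 else a / b

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_image <- function(image) {
  if (!(is.array(image) && length(dim(image)) == 3 && dim(image)[3] == 3)) {
    abort("`image` must be an H x W x 3 RGB array with intensities in [0, 255].")
  }
}
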