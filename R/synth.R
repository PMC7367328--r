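#' Specification of a synthetic H&E phantom
#'
#' Describes one synthetic hematoxylin-and-eosin tile: a pink eosin tissue
#' canvas, dark blue hematoxylin nucleus disks, thin white peri-nest "cracks"
#' (retraction artifact), large white inter-tissue gaps, a smooth
#' multiplicative illumination gradient with an optional dark lower-right
#' vignette, and additive Gaussian sensor noise. The default arguments are the
#' non-invasive (Ta) condition; [t1_spec()] returns the invasive (T1)
#' counterpart with more nuclei, pinker cytoplasm, and more crack area.
#'
#' @param image_size Pixels per side (square tile).
#' @param stage_label `"Ta"` or `"T1"`.
#' @param nucleus_count Expected nucleus count (Poisson mean, or exact count
#'   when `count_dist = "fixed"`).
#' @param count_dist `"poisson"` or `"fixed"`.
#' @param nucleus_radius_mean,nucleus_radius_sd Nucleus radius distribution in
#'   pixels (normal, truncated to `[2, mean + 3 sd]`).
#' @param nucleus_color,cytoplasm_color,background_color RGB triples in
#'   `[0, 255]`; background is the near-white non-tissue color used for cracks
#'   and gaps.
#' @param pinkness_shift Additive red-channel offset applied to the cytoplasm
#'   color (0 for Ta; positive for T1).
#' @param color_jitter_sd Per-image, per-channel Gaussian jitter of the
#'   cytoplasm color (staining variability between slides).
#' @param crack_fraction Target fraction of tile pixels covered by cracks.
#' @param crack_fraction_sdlog Per-image lognormal jitter of `crack_fraction`.
#' @param crack_width_range Integer range of crack band widths in pixels; kept
#'   strictly below the inter-tissue diameter rule so ground-truth classes are
#'   unambiguous.
#' @param gap_count Number of large white inter-tissue gaps.
#' @param gap_diameter Gap disk diameter in pixels; must exceed the 40-px
#'   inter-tissue diameter threshold.
#' @param illumination_gradient Peak-to-trough relative intensity of the
#'   multiplicative planar gradient (direction randomized per image).
#' @param vignette Logical; add a dark Gaussian spot at the lower-right corner.
#' @param vignette_strength,vignette_sigma_frac Depth (0..1) and scale (as a
#'   fraction of `image_size`) of the vignette.
#' @param noise_sd Additive Gaussian noise standard deviation in intensity
#'   units (applied last, then clipped to `[0, 255]`).
#' @param seed Integer seed; identical spec + seed gives bit-identical output.
#' @return A `phantom_spec` object (named list).
#' @examples
#' spec <- phantom_spec(nucleus_count = 30, seed = 1)
#' ph <- generate_phantom(spec)
#' dim(ph$image)
#' @export
phantom_spec <- function(image_size = 700,
                         stage_label = c("Ta", "T1"),
                         nucleus_count = 60,
                         count_dist = c("poisson", "fixed"),
                         nucleus_radius_mean = 7,
                         nucleus_radius_sd = 1.5,
                         nucleus_color = c(70, 60, 150),
                         cytoplasm_color = c(230, 180, 190),
                         background_color = c(250, 250, 250),
                         pinkness_shift = 0,
                         color_jitter_sd = 5,
                         crack_fraction = 0.010,
                         crack_fraction_sdlog = 0.35,
                         crack_width_range = c(1L, 5L),
                         gap_count = 3,
                         gap_diameter = 90,
                         illumination_gradient = 0.15,
                         vignette = TRUE,
                         vignette_strength = 0.3,
                         vignette_sigma_frac = 1 / 6,
                         noise_sd = 3,
                         seed = 1L) {
  spec <- list(
    image_size = as.integer(image_size),
    stage_label = match.arg(stage_label),
    nucleus_count = nucleus_count,
    count_dist = match.arg(count_dist),
    nucleus_radius_mean = nucleus_radius_mean,
    nucleus_radius_sd = nucleus_radius_sd,
    nucleus_color = nucleus_color,
    cytoplasm_color = cytoplasm_color,
    background_color = background_color,
    pinkness_shift = pinkness_shift,
    color_jitter_sd = color_jitter_sd,
    crack_fraction = crack_fraction,
    crack_fraction_sdlog = crack_fraction_sdlog,
    crack_width_range = as.integer(crack_width_range),
    gap_count = as.integer(gap_count),
    gap_diameter = gap_diameter,
    illumination_gradient = illumination_gradient,
    vignette = isTRUE(vignette),
    vignette_strength = vignette_strength,
    vignette_sigma_frac = vignette_sigma_frac,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

#' @rdname phantom_spec
#' @param ... Overrides passed to [phantom_spec()].
#' @export
ta_spec <- function(...) {
  args <- list(stage_label = "Ta", ...)
  do.call(phantom_spec, args)
}

#' @rdname phantom_spec
#' @export
t1_spec <- function(...) {
  defaults <- list(
    stage_label = "T1", nucleus_count = 120, nucleus_radius_mean = 9,
    nucleus_radius_sd = 2, pinkness_shift = 8, crack_fraction = 0.018
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(phantom_spec, args)
}

validate_phantom_spec <- function(spec) {
  colors <- c(spec$nucleus_color, spec$cytoplasm_color, spec$background_color)
  if (any(colors < 0) || any(colors > 255)) {
    abort("all color components must lie in [0, 255]")
  }
  if (spec$nucleus_radius_mean <= 0) abort("nucleus_radius_mean must be > 0")
  if (spec$image_size < 32) abort("image_size must be at least 32")
  if (spec$gap_count > 0 && spec$gap_diameter <= 40) {
    abort("gap_diameter must exceed the 40-px inter-tissue diameter threshold")
  }
  if (max(spec$crack_width_range) > 8) {
    abort("crack widths must stay thin (<= 8 px) so crack regions sit below the diameter threshold")
  }
  if (spec$crack_fraction < 0 || spec$crack_fraction > 0.2) {
    abort("crack_fraction must lie in [0, 0.2]")
  }
  invisible(spec)
}

# pixel set of a hard disk: included iff center distance <= radius (no
# anti-aliasing), clipped to the image; returns a 2-column index matrix
disk_pixels <- function(center_r, center_c, radius, n) {
  rr <- max(1, floor(center_r - radius)):min(n, ceiling(center_r + radius))
  cc <- max(1, floor(center_c - radius)):min(n, ceiling(center_c + radius))
  r <- rep(rr, times = length(cc)); c_ <- rep(cc, each = length(rr))
  keep <- (r - center_r)^2 + (c_ - center_c)^2 <= radius^2
  cbind(r[keep], c_[keep])
}

ring_pixels <- function(center_r, center_c, r_in, r_out, n) {
  rr <- max(1, floor(center_r - r_out)):min(n, ceiling(center_r + r_out))
  cc <- max(1, floor(center_c - r_out)):min(n, ceiling(center_c + r_out))
  r <- rep(rr, times = length(cc)); c_ <- rep(cc, each = length(rr))
  d2 <- (r - center_r)^2 + (c_ - center_c)^2
  keep <- d2 > r_in^2 & d2 <= r_out^2
  cbind(r[keep], c_[keep])
}

#' Generate one synthetic H&E phantom with ground truth
#'
#' Rasterizes the scene described by a [phantom_spec()]: white gaps are drawn
#' first, then non-overlapping nucleus disks are placed by bounded rejection
#' sampling, then thin white crack bands are drawn around well-separated
#' nuclei until the target crack area is reached. All ground-truth masks are
#' frozen before the multiplicative illumination field and additive noise are
#' applied, so extractors can be validated against pre-illumination truth.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `he_phantom` with elements `image` (H x W x 3 array,
#'   0..255 integers), `truth` (list: `nucleus_centers` tibble with `row`,
#'   `col`, `radius`; masks `nucleus_mask`, `crack_mask`, `gap_mask`,
#'   `tissue_mask`; `stage_label`; `pre_illumination` image array), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  n <- spec$image_size
  npx <- n * n

  cyto_col <- spec$cytoplasm_color + rnorm(3, 0, spec$color_jitter_sd)
  cyto_col[1] <- cyto_col[1] + spec$pinkness_shift
  cyto_col <- clip(cyto_col)
  nuc_col <- clip(spec$nucleus_color + rnorm(3, 0, spec$color_jitter_sd / 2))
  bg_col <- spec$background_color

  image <- array(0, dim = c(n, n, 3))
  for (ch in 1:3) image[, , ch] <- cyto_col[ch]

  # --- large white inter-tissue gaps -------------------------------------
  gap_mask <- matrix(FALSE, n, n)
  if (spec$gap_count > 0) {
    r_gap <- spec$gap_diameter / 2
    if (n < 2 * (r_gap + 1)) abort("image too small for the requested gap diameter")
    for (i in seq_len(spec$gap_count)) {
      cr <- runif(1, r_gap + 1, n - r_gap)
      cc <- runif(1, r_gap + 1, n - r_gap)
      px <- disk_pixels(cr, cc, r_gap, n)
      gap_mask[px] <- TRUE
    }
  }
  # keep-out zone so cracks and nuclei never touch a gap (8-connectivity safe)
  gap_keepout <- if (any(gap_mask)) {
    EBImage::dilate(gap_mask, EBImage::makeBrush(5, "disc")) > 0
  } else {
    gap_mask
  }

  # --- nucleus placement by bounded rejection sampling -------------------
  n_nuc <- switch(spec$count_dist,
    poisson = rpois(1, spec$nucleus_count),
    fixed = round(spec$nucleus_count)
  )
  radii <- numeric(0)
  centers <- matrix(numeric(0), ncol = 2)
  r_hi <- spec$nucleus_radius_mean + 3 * spec$nucleus_radius_sd
  attempts <- 0
  max_attempts <- 200 * max(n_nuc, 1)
  while (nrow(centers) < n_nuc) {
    attempts <- attempts + 1
    if (attempts > max_attempts) {
      abort(sprintf(
        "unable to place %d non-overlapping nuclei in a %d x %d tile (packing unsatisfiable)",
        n_nuc, n, n
      ))
    }
    r <- min(max(rnorm(1, spec$nucleus_radius_mean, spec$nucleus_radius_sd), 2), r_hi)
    cr <- runif(1, r + 1, n - r)
    cc <- runif(1, r + 1, n - r)
    if (nrow(centers) > 0) {
      d <- sqrt((centers[, 1] - cr)^2 + (centers[, 2] - cc)^2)
      if (any(d <= radii + r + 2.5)) next
    }
    px <- disk_pixels(cr, cc, r, n)
    if (any(gap_keepout[px])) next
    centers <- rbind(centers, c(cr, cc))
    radii <- c(radii, r)
  }

  nucleus_mask <- matrix(FALSE, n, n)
  if (n_nuc > 0) {
    for (i in seq_len(n_nuc)) {
      px <- disk_pixels(centers[i, 1], centers[i, 2], radii[i], n)
      nucleus_mask[px] <- TRUE
    }
  }

  # --- thin crack bands around well-separated nuclei ---------------------
  crack_mask <- matrix(FALSE, n, n)
  target_crack <- round(spec$crack_fraction *
    exp(rnorm(1, 0, spec$crack_fraction_sdlog)) * npx)
  if (target_crack > 0 && n_nuc > 0) {
    order_idx <- sample.int(n_nuc)
    ringed <- integer(0)
    w_lo <- spec$crack_width_range[1]
    w_hi <- spec$crack_width_range[2]
    for (i in order_idx) {
      if (sum(crack_mask) >= target_crack) break
      # rings around distinct nuclei must never merge into one component
      if (length(ringed) > 0) {
        d <- sqrt((centers[ringed, 1] - centers[i, 1])^2 +
                    (centers[ringed, 2] - centers[i, 2])^2)
        if (any(d <= radii[ringed] + radii[i] + 2 * (2 + w_hi) + 2)) next
      }
      w <- sample(w_lo:w_hi, 1)
      px <- ring_pixels(centers[i, 1], centers[i, 2], radii[i] + 2,
                        radii[i] + 2 + w, n)
      keep <- !nucleus_mask[px] & !gap_keepout[px]
      px <- px[keep, , drop = FALSE]
      if (nrow(px) == 0) next
      crack_mask[px] <- TRUE
      ringed <- c(ringed, i)
    }
  }

  tissue_mask <- !(crack_mask | gap_mask)

  for (ch in 1:3) {
    plane <- image[, , ch]
    plane[nucleus_mask] <- nuc_col[ch]
    plane[crack_mask | gap_mask] <- bg_col[ch]
    image[, , ch] <- plane
  }
  pre_illum <- image

  # --- illumination field (after ground truth is frozen) -----------------
  field <- matrix(1, n, n)
  if (spec$illumination_gradient > 0) {
    theta <- runif(1, 0, 2 * pi)
    proj <- outer(seq_len(n), seq_len(n),
                  function(r, c) r * sin(theta) + c * cos(theta))
    t01 <- (proj - min(proj)) / (max(proj) - min(proj))
    field <- field * (1 + spec$illumination_gradient * (t01 - 0.5))
  }
  if (spec$vignette) {
    s <- spec$vignette_sigma_frac * n
    d2 <- outer((seq_len(n) - n)^2, (seq_len(n) - n)^2, "+")
    field <- field * (1 - spec$vignette_strength * exp(-d2 / (2 * s^2)))
  }
  for (ch in 1:3) image[, , ch] <- image[, , ch] * field

  if (spec$noise_sd > 0) {
    image <- image + array(rnorm(length(image), 0, spec$noise_sd), dim = dim(image))
  }
  image <- round(clip(image))

  truth <- list(
    nucleus_centers = tibble(
      row = if (n_nuc > 0) centers[, 1] else numeric(0),
      col = if (n_nuc > 0) centers[, 2] else numeric(0),
      radius = radii
    ),
    nucleus_mask = nucleus_mask,
    crack_mask = crack_mask,
    gap_mask = gap_mask,
    tissue_mask = tissue_mask,
    stage_label = spec$stage_label,
    pre_illumination = pre_illum
  )
  structure(list(image = image, truth = truth, spec = spec),
            class = "he_phantom")
}

#' Generate a labeled synthetic dataset manifest
#'
#' Returns a manifest of deterministic per-image child specs rather than the
#' images themselves (a 200-image dataset would not fit in memory); images are
#' rasterized on demand with [phantom_for_row()] or streamed through
#' [extract_feature_table()].
#'
#' @param n_ta,n_t1 Number of non-invasive (Ta) and invasive (T1) images.
#' @param ta_spec,t1_spec Class-level [phantom_spec()]s; per-image seeds are
#'   derived deterministically from `seed`.
#' @param seed Master seed.
#' @return A tibble of class `phantom_dataset` with columns `image_id`,
#'   `stage`, `seed`, and a `spec` list-column.
#' @examples
#' ds <- generate_dataset(3, 5, seed = 7)
#' table(ds$stage)
#' @export
generate_dataset <- function(n_ta, n_t1, ta_spec = hestage::ta_spec(),
                             t1_spec = hestage::t1_spec(), seed = 1L) {
  if (n_ta < 1 || n_t1 < 1) abort("n_ta and n_t1 must both be >= 1")
  n <- n_ta + n_t1
  child_seeds <- vapply(seq_len(n), function(i) derive_seed(seed, i), integer(1))
  stage <- c(rep("Ta", n_ta), rep("T1", n_t1))
  specs <- lapply(seq_len(n), function(i) {
    base <- if (stage[i] == "Ta") ta_spec else t1_spec
    base$seed <- child_seeds[i]
    base
  })
  out <- tibble(
    image_id = sprintf("img_%s_%03d", tolower(stage), seq_len(n)),
    stage = stage,
    seed = child_seeds,
    spec = specs
  )
  class(out) <- c("phantom_dataset", class(out))
  out
}

#' Rasterize one row of a phantom dataset manifest
#'
#' @param dataset A [generate_dataset()] manifest.
#' @param i Row index.
#' @return An `he_phantom` (see [generate_phantom()]).
#' @export
phantom_for_row <- function(dataset, i) {
  generate_phantom(dataset$spec[[i]])
}

#' Write a phantom dataset to disk
#'
#' Writes each image as PNG (or TIFF), its ground-truth masks as PNG, a JSON
#' sidecar with nucleus centers and the stage label, and a `manifest.csv`
#' (filename, label, seed).
#'
#' @param dataset A [generate_dataset()] manifest.
#' @param dir Output directory (created if needed).
#' @param format `"png"` or `"tiff"`.
#' @param write_masks Logical; also write ground-truth masks.
#' @return The manifest tibble with a `filename` column, invisibly.
#' @export
write_phantom_dataset <- function(dataset, dir, format = c("png", "tiff"),
                                  write_masks = TRUE) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(nrow(dataset))
  for (i in seq_len(nrow(dataset))) {
    ph <- phantom_for_row(dataset, i)
    stem <- dataset$image_id[i]
    files[i] <- file.path(dir, paste0(stem, ".", format))
    write_rgb_image(ph$image, files[i])
    jsonlite::write_json(
      list(
        image_id = stem, stage = ph$truth$stage_label,
        seed = dataset$seed[i],
        nucleus_centers = ph$truth$nucleus_centers
      ),
      file.path(dir, paste0(stem, ".json")),
      auto_unbox = TRUE, digits = NA
    )
    if (write_masks) {
      for (m in c("nucleus_mask", "crack_mask", "gap_mask", "tissue_mask")) {
        png::writePNG(t(ph$truth[[m]]) * 1,
                      file.path(dir, paste0(stem, "_", m, ".png")))
      }
    }
  }
  manifest <- tibble(filename = basename(files), label = dataset$stage,
                     seed = dataset$seed)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  out <- dataset
  out$filename <- files
  invisible(out)
}
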