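# Independent oracles and small fixture builders shared across tests.

# uniform-color RGB array
solid_image <- function(h, w, rgb) {
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}

# paint a hard disk (center distance <= radius) onto an image, by brute force
paint_disk <- function(img, cr, cc, r, rgb) {
  for (x in -ceiling(r):ceiling(r)) {
    for (y in -ceiling(r):ceiling(r)) {
      if (x^2 + y^2 <= r^2) img[cr + x, cc + y, ] <- rgb
    }
  }
  img
}

# brute-force pixel count of a rasterized disk
oracle_disk_area <- function(r) {
  s <- 0L
  for (x in -ceiling(r):ceiling(r)) {
    for (y in -ceiling(r):ceiling(r)) {
      if (x^2 + y^2 <= r^2) s <- s + 1L
    }
  }
  s
}

# exposed-edge perimeter of a binary matrix, counted pixel by pixel (an
# intentionally naive second route, independent of the package's shifts)
oracle_perimeter <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- 0L
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (!m[i, j]) next
      if (i == 1 || !m[i - 1, j]) p <- p + 1L
      if (i == h || !m[i + 1, j]) p <- p + 1L
      if (j == 1 || !m[i, j - 1]) p <- p + 1L
      if (j == w || !m[i, j + 1]) p <- p + 1L
    }
  }
  p
}

# frontier-based flood-fill labeling with 8-connectivity: an independent
# labeling route (no EBImage, no igraph)
oracle_label8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] > 0) next
    cur <- cur + 1L
    frontier <- start
    lab[start] <- cur
    while (length(frontier) > 0) {
      r <- ((frontier - 1) %% h) + 1
      c_ <- ((frontier - 1) %/% h) + 1
      nbr_r <- c(r - 1, r - 1, r - 1, r, r, r + 1, r + 1, r + 1)
      nbr_c <- c(c_ - 1, c_, c_ + 1, c_ - 1, c_ + 1, c_ - 1, c_, c_ + 1)
      ok <- nbr_r >= 1 & nbr_r <= h & nbr_c >= 1 & nbr_c <= w
      idx <- (nbr_c[ok] - 1) * h + nbr_r[ok]
      idx <- unique(idx[mask[idx] & lab[idx] == 0])
      lab[idx] <- cur
      frontier <- idx
    }
  }
  lab
}

# classify each oracle region as inter-tissue by the strict diameter rule
oracle_classify <- function(mask, threshold = 40, method = "equivalent") {
  lab <- oracle_label8(mask)
  k <- max(lab)
  inter <- matrix(FALSE, nrow(mask), ncol(mask))
  if (k == 0) return(list(inter = inter, crack = inter))
  for (i in seq_len(k)) {
    px <- which(lab == i)
    if (method == "equivalent") {
      diam <- 2 * sqrt(length(px) / pi)
    } else {
      h <- nrow(mask)
      r <- ((px - 1) %% h) + 1
      c_ <- ((px - 1) %/% h) + 1
      pts <- cbind(c(r - 0.5, r - 0.5, r + 0.5, r + 0.5),
                   c(c_ - 0.5, c_ + 0.5, c_ - 0.5, c_ + 0.5))
      diam <- max(dist(pts))
    }
    if (diam > threshold) inter[px] <- TRUE
  }
  list(inter = inter, crack = mask & !inter)
}

# random blobby binary mask (smoothed noise, thresholded)
random_blob_mask <- function(n = 64, sigma = 2, frac = 0.3) {
  x <- matrix(runif(n * n), n, n)
  s <- EBImage::gblur(x, sigma = sigma)
  s > quantile(s, 1 - frac)
}

# pairwise Mann-Whitney AUC by explicit positive-negative comparison
oracle_auc_pairs <- function(scores, labels) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  cmp <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# small labeled gaussian-blob table for classifier tests
blob_table <- function(n_per_class = 50, p = 2, sep = 3, seed = 1) {
  set.seed(seed)
  x0 <- matrix(rnorm(n_per_class * p), n_per_class, p)
  x1 <- matrix(rnorm(n_per_class * p, mean = sep), n_per_class, p)
  df <- as.data.frame(rbind(x0, x1))
  names(df) <- paste0("f", seq_len(p))
  df$stage <- rep(c("Ta", "T1"), each = n_per_class)
  tibble::as_tibble(df)
}

# tiny phantom spec for fast tests
tiny_spec <- function(stage = "Ta", ...) {
  base <- list(
    image_size = 256, stage_label = stage, nucleus_count = 20,
    nucleus_radius_mean = 6, nucleus_radius_sd = 1,
    gap_count = 1, gap_diameter = 60, crack_fraction = 0.01,
    noise_sd = 0, illumination_gradient = 0, vignette = FALSE,
    color_jitter_sd = 0, seed = 1L
  )
  do.call(phantom_spec, utils::modifyList(base, list(...)))
}
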