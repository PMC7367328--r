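# Connected-component labeling with 8-connectivity: EBImage::bwlabel is
# 4-connected, so diagonally touching 4-components are merged through an
# adjacency graph. Labels are renumbered 1..k in first-pixel order.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  k <- max(lab)
  if (k <= 1) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  pairs <- NULL
  for (sh in list(c(1L, 1L), c(1L, -1L))) {
    dr <- sh[1]; dc <- sh[2]
    r1 <- if (dr == 1) 1:(h - 1) else 2:h
    r2 <- if (dr == 1) 2:h else 1:(h - 1)
    c1 <- if (dc == 1) 1:(w - 1) else 2:w
    c2 <- if (dc == 1) 2:w else 1:(w - 1)
    a <- lab[r1, c1]; b <- lab[r2, c2]
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], b[sel]))
  }
  if (is.null(pairs)) {
    relabeled <- lab
  } else {
    g <- igraph::graph_from_edgelist(unique(pairs), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, k - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    relabeled <- lab
    relabeled[lab > 0] <- comp[lab[lab > 0]]
  }
  # renumber in order of first appearance (column-major scan), densely
  ids <- relabeled[relabeled > 0]
  first <- !duplicated(ids)
  remap <- integer(max(ids))
  remap[ids[first]] <- seq_len(sum(first))
  relabeled[relabeled > 0] <- remap[ids]
  relabeled
}

# area of the convex hull of the pixel *corners* of a region (so a filled
# rectangle has hull area equal to its pixel count and solidity is <= 1);
# only boundary pixels matter for the hull
hull_area_pixels <- function(rows, cols) {
  if (length(rows) == 1) return(1)
  pts_r <- c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5)
  pts_c <- c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5)
  hull <- grDevices::chull(pts_c, pts_r)
  hc <- pts_c[hull]; hr <- pts_r[hull]
  abs(sum(hc * c(hr[-1], hr[1]) - c(hc[-1], hc[1]) * hr)) / 2
}

# shape measures of one region given its pixel coordinates. Second moments
# include the 1/12 per-pixel term so degenerate 1-px-wide shapes have a
# positive minor axis and eccentricity strictly below 1. `hull_rows/cols`
# restrict the convex-hull computation (boundary pixels suffice).
region_shape <- function(rows, cols, edge_perimeter, corner_count,
                         hull_rows = rows, hull_cols = cols) {
  area <- length(rows)
  mu_r <- mean(rows); mu_c <- mean(cols)
  vrr <- mean((rows - mu_r)^2) + 1 / 12
  vcc <- mean((cols - mu_c)^2) + 1 / 12
  vrc <- mean((rows - mu_r) * (cols - mu_c))
  tr <- vrr + vcc
  det_ <- vrr * vcc - vrc^2
  disc <- sqrt(max(0, (tr / 2)^2 - det_))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, 1e-12)
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(l2)
  conv <- max(hull_area_pixels(hull_rows, hull_cols), area)
  bbox <- (diff(range(rows)) + 1) * (diff(range(cols)) + 1)
  # corner-corrected perimeter tracks the true boundary length of smooth
  # shapes; floored at the equal-area circle so form_factor <= 1
  p_smooth <- max(edge_perimeter - (2 - sqrt(2)) * corner_count,
                  2 * sqrt(pi * area))
  c(
    area = area,
    perimeter = edge_perimeter,
    equiv_diameter = 2 * sqrt(area / pi),
    major_axis = major,
    minor_axis = minor,
    aspect_ratio = major / minor,
    eccentricity = sqrt(max(0, 1 - l2 / l1)),
    orientation = 0.5 * atan2(2 * vrc, vcc - vrr),
    solidity = area / conv,
    extent = area / bbox,
    form_factor = 4 * pi * area / p_smooth^2,
    compactness = edge_perimeter^2 / (4 * pi * area),
    convex_area = conv,
    bbox_area = bbox
  )
}

# exposed-edge perimeter and 2x2-configuration corner count of a binary
# matrix (the whole matrix is one region; callers pass a bbox crop)
perimeter_and_corners <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(FALSE, h + 2, w + 2)
  p[2:(h + 1), 2:(w + 1)] <- m
  up <- p[2:(h + 1), 2:(w + 1)] & !p[1:h, 2:(w + 1)]
  dn <- p[2:(h + 1), 2:(w + 1)] & !p[3:(h + 2), 2:(w + 1)]
  lf <- p[2:(h + 1), 2:(w + 1)] & !p[2:(h + 1), 1:w]
  rt <- p[2:(h + 1), 2:(w + 1)] & !p[2:(h + 1), 3:(w + 2)]
  edges <- sum(up) + sum(dn) + sum(lf) + sum(rt)
  boundary <- up | dn | lf | rt
  # 2x2 windows: 1 or 3 foreground pixels are single corners, two diagonal
  # foreground pixels contribute two corners
  a <- p[1:(h + 1), 1:(w + 1)]; b <- p[1:(h + 1), 2:(w + 2)]
  c_ <- p[2:(h + 2), 1:(w + 1)]; d <- p[2:(h + 2), 2:(w + 2)]
  s <- a + b + c_ + d
  diag2 <- (s == 2) & ((a & d) | (b & c_))
  corners <- sum(s == 1) + sum(s == 3) + 2 * sum(diag2)
  list(edges = edges, corners = corners, boundary = boundary)
}

# full region-properties table for a labeled matrix; intensity statistics are
# added per channel when an RGB image is supplied
region_props <- function(labels, image = NULL) {
  k <- max(labels)
  empty <- tibble(
    label = integer(0), centroid_row = numeric(0), centroid_col = numeric(0)
  )
  if (k == 0) return(empty)
  idx <- which(labels > 0)
  lab_vec <- labels[idx]
  h <- nrow(labels)
  rows_all <- ((idx - 1) %% h) + 1
  cols_all <- ((idx - 1) %/% h) + 1
  ord <- order(lab_vec)
  runs <- rle(lab_vec[ord])
  run_ends <- cumsum(runs$lengths)
  run_starts <- run_ends - runs$lengths + 1
  by_label <- lapply(seq_along(runs$values), function(i) {
    ord[run_starts[i]:run_ends[i]]
  })
  names(by_label) <- runs$values

  if (!is.null(image)) {
    chans <- list(red = image[, , 1][idx], green = image[, , 2][idx],
                  blue = image[, , 3][idx])
  }

  out <- vector("list", k)
  for (li in seq_along(by_label)) {
    sel <- by_label[[li]]
    rows <- rows_all[sel]; cols <- cols_all[sel]
    r0 <- min(rows); c0 <- min(cols)
    crop <- matrix(FALSE, max(rows) - r0 + 1, max(cols) - c0 + 1)
    crop[cbind(rows - r0 + 1, cols - c0 + 1)] <- TRUE
    pc <- perimeter_and_corners(crop)
    bidx <- which(pc$boundary)
    hrows <- ((bidx - 1) %% nrow(crop)) + r0
    hcols <- ((bidx - 1) %/% nrow(crop)) + c0
    shape <- region_shape(rows, cols, pc$edges, pc$corners, hrows, hcols)
    rec <- c(label = as.integer(names(by_label)[li]), shape,
             centroid_row = mean(rows), centroid_col = mean(cols))
    if (!is.null(image)) {
      for (ch in names(chans)) {
        v <- chans[[ch]][sel]
        rec <- c(rec, setNames(
          c(mean(v), if (length(v) > 1) sd(v) else 0, min(v), max(v), median(v)),
          paste0(ch, "_", c("mean", "sd", "min", "max", "median"))
        ))
      }
    }
    out[[li]] <- rec
  }
  as_tibble(do.call(rbind, out))
}

# symmetric normalized gray-level co-occurrence matrix statistics for pixels
# inside `mask`, at displacement (dr, dc); `q` is an integer matrix of gray
# levels 1..nlevels
glcm_stats <- function(q, mask, dr, dc, nlevels = 8) {
  h <- nrow(q); w <- ncol(q)
  r1 <- max(1, 1 - dr):min(h, h - dr)
  c1 <- max(1, 1 - dc):min(w, w - dc)
  if (length(r1) == 0 || length(c1) == 0) return(glcm_zero())
  ok <- which(mask[r1, c1] & mask[r1 + dr, c1 + dc])
  if (length(ok) == 0) return(glcm_zero())
  a <- q[r1, c1][ok]; b <- q[r1 + dr, c1 + dc][ok]
  code <- c((a - 1L) * nlevels + b, (b - 1L) * nlevels + a) # symmetric
  P <- tabulate(code, nlevels * nlevels)
  P <- matrix(P / sum(P), nlevels, nlevels, byrow = TRUE)
  i <- .row(dim(P)); j <- .col(dim(P))
  px <- rowSums(P)
  mu <- sum(seq_len(nlevels) * px)
  sig2 <- sum((seq_len(nlevels) - mu)^2 * px)
  nz <- P > 0
  # sum / difference distributions over the 8x8 table
  psum <- vapply(2:(2 * nlevels), function(k) sum(P[i + j == k]), numeric(1))
  pdif <- vapply(0:(nlevels - 1), function(k) sum(P[abs(i - j) == k]), numeric(1))
  ks <- 2:(2 * nlevels); kd <- 0:(nlevels - 1)
  sa <- sum(ks * psum)
  da <- sum(kd * pdif)
  c(
    contrast = sum((i - j)^2 * P),
    dissimilarity = sum(abs(i - j) * P),
    homogeneity = sum(P / (1 + (i - j)^2)),
    asm = sum(P^2),
    energy = sqrt(sum(P^2)),
    entropy = -sum(P[nz] * log2(P[nz])),
    correlation = if (sig2 > 0) sum((i - mu) * (j - mu) * P) / sig2 else 0,
    variance = sig2,
    sum_average = sa,
    sum_variance = sum((ks - sa)^2 * psum),
    sum_entropy = -sum(psum[psum > 0] * log2(psum[psum > 0])),
    diff_variance = sum((kd - da)^2 * pdif),
    diff_entropy = -sum(pdif[pdif > 0] * log2(pdif[pdif > 0]))
  )
}

glcm_zero <- function() {
  setNames(rep(0, 13), glcm_stat_names)
}
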