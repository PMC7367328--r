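#' Principal component analysis of a feature table
#'
#' Columns are centered and (by default) scaled to unit variance; constant
#' columns are dropped before scaling. Components are ordered by eigenvalue
#' (the variance each component explains).
#'
#' @param table Feature table (numeric feature columns, optional
#'   `image_id`/`stage` kept aside).
#' @param standardize Logical; scale columns to unit variance.
#' @param label Label column name retained alongside the projection.
#' @return A `stage_pca` object: `eigenvalues`, `loadings` (orthonormal
#'   columns), `scores` tibble of projected coordinates (plus label column if
#'   present), and `dropped` (constant columns).
#' @export
pca_features <- function(table, standardize = TRUE, label = "stage") {
  feat_cols <- setdiff(names(table)[vapply(table, is.numeric, logical(1))], label)
  x <- as.matrix(as.data.frame(table[, feat_cols]))
  if (nrow(x) < 2) abort("PCA needs at least 2 rows")
  if (nrow(unique(as.data.frame(x))) < 2) abort("PCA needs at least 2 distinct rows")
  sds <- apply(x, 2, sd)
  dropped <- character(0)
  if (standardize && any(sds == 0)) {
    dropped <- feat_cols[sds == 0]
    message(sprintf("dropping %d constant column(s) before standardizing", length(dropped)))
    x <- x[, sds > 0, drop = FALSE]
  }
  fit <- prcomp(x, center = TRUE, scale. = standardize)
  scores <- as_tibble(fit$x)
  if (!is.null(label) && label %in% names(table)) scores[[label]] <- table[[label]]
  if ("image_id" %in% names(table)) scores$image_id <- table$image_id
  structure(list(
    eigenvalues = fit$sdev^2,
    loadings = fit$rotation,
    scores = scores,
    center = fit$center, scale = fit$scale,
    standardize = standardize, dropped = dropped
  ), class = "stage_pca")
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1) + 1) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- x[sample.int(n, 1, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

#' k-means sweep over a range of cluster counts
#'
#' Lloyd's algorithm with k-means++ seeding, best of `restarts` runs by
#' within-cluster sum of squares, for every k in `k_range`.
#'
#' @param coords Numeric matrix or the `scores` of a [pca_features()] result
#'   (a `stage_pca` may be passed directly; the first `n_components` are
#'   used).
#' @param k_range Cluster counts to try (default 2..9).
#' @param seed Integer seed.
#' @param restarts Independent seedings per k (default 10).
#' @param n_components When `coords` is a `stage_pca`: number of leading
#'   components, default enough for 90% cumulative eigenvalue mass, capped at
#'   50.
#' @return A tibble with one row per k: `k`, `wcss`, and an `assignment`
#'   list-column of integer cluster labels.
#' @export
kmeans_sweep <- function(coords, k_range = 2:9, seed = 1L, restarts = 10,
                         n_components = NULL) {
  if (inherits(coords, "stage_pca")) {
    ev <- coords$eigenvalues
    if (is.null(n_components)) {
      n_components <- min(which(cumsum(ev) / sum(ev) >= 0.9), 50)
    }
    sc <- coords$scores
    pc_cols <- grep("^PC", names(sc), value = TRUE)
    coords <- as.matrix(sc[, pc_cols[seq_len(min(n_components, length(pc_cols)))]])
  }
  coords <- as.matrix(coords)
  if (max(k_range) > nrow(coords)) abort("k exceeds the number of rows")
  rows <- lapply(k_range, function(k) {
    best <- NULL
    for (r in seq_len(restarts)) {
      set.seed(derive_seed(seed, k * 1000 + r))
      init <- kmeanspp_centers(coords, k)
      fit <- suppressWarnings(
        kmeans(coords, centers = init, iter.max = 100, algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    tibble(k = k, wcss = best$tot.withinss, assignment = list(best$cluster))
  })
  bind_rows(rows)
}

#' Information gain of a clustering about the labels
#'
#' `IG = H(labels) - sum_j (n_j / n) H(labels | cluster j)` with base-2
#' entropies and the convention `0 log 0 = 0`. Zero when clusters carry no
#' label information; at most `H(labels)`.
#'
#' @param labels Class labels.
#' @param assignments Cluster assignments of the same length.
#' @return Information gain in bits (non-negative).
#' @export
information_gain <- function(labels, assignments) {
  if (length(labels) == 0) abort("empty input")
  if (length(labels) != length(assignments)) abort("length mismatch")
  H <- function(v) {
    p <- table(v) / length(v)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  h0 <- H(labels)
  cond <- 0
  for (cl in unique(assignments)) {
    sel <- assignments == cl
    cond <- cond + sum(sel) / length(labels) * H(labels[sel])
  }
  max(0, h0 - cond)
}

#' @export
print.stage_pca <- function(x, ...) {
  ev <- x$eigenvalues
  cat(sprintf("<stage_pca> %d components; first 3 eigenvalue fractions: %s\n",
              length(ev),
              paste(sprintf("%.3f", head(ev / sum(ev), 3)), collapse = ", ")))
  invisible(x)
}
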