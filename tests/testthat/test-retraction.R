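white <- c(250, 250, 250)
pink <- c(230, 180, 190)

test_that("single regions classify by the strict diameter rule", {
  # disk radius 25: equivalent diameter ~50 > 40 -> inter-tissue
  img <- paint_disk(solid_image(128, 128, pink), 64, 64, 25, white)
  seg <- segment_cracks(img)
  expect_equal(sum(seg$crack_mask), 0)
  expect_equal(sum(seg$intertissue_mask), oracle_disk_area(25))

  # 5x5 square: equivalent diameter 2*sqrt(25/pi) ~ 5.64 <= 40 -> crack
  img2 <- solid_image(64, 64, pink)
  img2[30:34, 30:34, ] <- rep(white, each = 25)
  seg2 <- segment_cracks(img2)
  expect_equal(sum(seg2$crack_mask), 25)
  expect_equal(sum(seg2$intertissue_mask), 0)
  expect_equal(seg2$diameters, 2 * sqrt(25 / pi), tolerance = 1e-12)
})

test_that("the area threshold boundary at 40 px diameter is strict", {
  # area 1257 -> diameter 40.007... > 40; area 1256 -> 39.99 <= 40
  mk <- function(area) {
    img <- solid_image(80, 80, pink)
    base <- matrix(FALSE, 80, 80)
    full_rows <- area %/% 40
    base[10 + seq_len(full_rows), 21:60] <- TRUE
    rem <- area - full_rows * 40
    if (rem > 0) base[10 + full_rows + 1, 21:(20 + rem)] <- TRUE
    for (ch in 1:3) {
      plane <- img[, , ch]; plane[base] <- white[ch]; img[, , ch] <- plane
    }
    img
  }
  seg_hi <- segment_cracks(mk(1257))
  expect_equal(sum(seg_hi$intertissue_mask), 1257)
  expect_equal(sum(seg_hi$crack_mask), 0)
  seg_lo <- segment_cracks(mk(1256))
  expect_equal(sum(seg_lo$crack_mask), 1256)
  expect_equal(sum(seg_lo$intertissue_mask), 0)
})

test_that("crack and inter-tissue masks partition the non-tissue mask", {
  for (s in 1:5) {
    set.seed(s)
    mask <- random_blob_mask(64, sigma = runif(1, 1, 4), frac = runif(1, 0.2, 0.5))
    res <- hestage:::classify_nontissue(mask, 40)
    expect_false(any(res$crack_mask & res$intertissue_mask))
    expect_identical(res$crack_mask | res$intertissue_mask, mask)
  }
})

test_that("raising the diameter threshold never shrinks the crack mask", {
  set.seed(42)
  mask <- random_blob_mask(96, sigma = 3, frac = 0.4)
  prev <- hestage:::classify_nontissue(mask, 5)$crack_mask
  for (thr in c(10, 20, 40, 80)) {
    cur <- hestage:::classify_nontissue(mask, thr)$crack_mask
    expect_true(all(cur[prev])) # previous crack pixels stay cracks
    prev <- cur
  }
})

test_that("region classification agrees with the flood-fill oracle (both diameter rules)", {
  set.seed(7)
  for (trial in 1:60) {
    mask <- random_blob_mask(64, sigma = runif(1, 1, 5), frac = runif(1, 0.1, 0.5))
    thr <- sample(c(5, 10, 40), 1)
    res <- hestage:::classify_nontissue(mask, thr)
    orc <- oracle_classify(mask, thr)
    expect_identical(res$intertissue_mask, orc$inter)
    if (trial <= 20) {
      resf <- hestage:::classify_nontissue(mask, thr, diameter_method = "feret")
      orcf <- oracle_classify(mask, thr, method = "feret")
      expect_identical(resf$intertissue_mask, orcf$inter)
    }
  }
})

test_that("crack features compute the stated arithmetic", {
  # three rectangular crack components of areas 10, 20, 30
  crack <- matrix(FALSE, 64, 64)
  crack[5:6, 5:9] <- TRUE    # 10 px
  crack[20:23, 5:9] <- TRUE  # 20 px
  crack[40:44, 5:10] <- TRUE # 30 px
  inter <- matrix(FALSE, 64, 64)
  tissue <- !crack
  f <- crack_features(crack, inter, tissue)
  expect_equal(unname(f["crack_pixel_count"]), 60)
  expect_equal(unname(f["crack_component_count"]), 3)
  expect_equal(unname(f["crack_area_mean"]), 20)
  expect_equal(unname(f["crack_area_max"]), 30)
  expect_equal(unname(f["crack_area_median"]), 20)
  expect_equal(unname(f["sample_ratio"]), mean(tissue))
  expect_length(f, 15)
  expect_named(f, hestage:::retraction_feature_names())
})

test_that("empty crack mask zeroes crack statistics but keeps background features", {
  none <- matrix(FALSE, 32, 32)
  tissue <- matrix(TRUE, 32, 32); tissue[1:4, ] <- FALSE
  f <- crack_features(none, none, tissue)
  crack_stats <- setdiff(names(f), c("sample_ratio", "nontissue_fraction"))
  expect_true(all(f[crack_stats] == 0))
  expect_equal(unname(f["sample_ratio"]), mean(tissue))
  expect_equal(unname(f["nontissue_fraction"]), 1 - mean(tissue))
  # empty tissue mask: densities defined 0 with a warning
  expect_warning(f2 <- crack_features(none, none, none), "empty tissue")
  expect_equal(unname(f2["crack_edge_density"]), 0)
})

test_that("generator crack area is recovered through the full segmentation", {
  ph <- generate_phantom(tiny_spec(stage = "T1", crack_fraction = 0.015,
                                   nucleus_count = 25, seed = 13))
  seg <- segment_cracks(ph$truth$pre_illumination)
  truth_area <- sum(ph$truth$crack_mask)
  expect_gt(truth_area, 0)
  expect_lt(abs(sum(seg$crack_mask) - truth_area) / truth_area, 0.05)
})
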