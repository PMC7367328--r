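pink <- c(230, 180, 190)
blue <- c(70, 60, 150)

test_that("well-separated blue disks are segmented with oracle-exact areas", {
  img <- solid_image(300, 300, pink)
  centers <- rbind(c(50, 50), c(50, 150), c(150, 50), c(150, 150), c(250, 250))
  for (i in 1:5) img <- paint_disk(img, centers[i, 1], centers[i, 2], 8, blue)
  seg <- segment_nuclei(img)
  expect_equal(max(seg$labels), 5)
  areas <- tabulate(seg$labels[seg$labels > 0])
  expect_equal(areas, rep(oracle_disk_area(8), 5))
})

test_that("blank pink tiles have no nuclei and small debris is filtered", {
  expect_equal(max(segment_nuclei(solid_image(64, 64, pink))$labels), 0)
  img <- paint_disk(solid_image(128, 128, pink), 64, 64, 8, blue)
  img[10, 10:19, ] <- rep(blue, each = 10) # 10-px speck, below the 20-px rule
  seg <- segment_nuclei(img)
  expect_equal(max(seg$labels), 1)
  expect_equal(sum(seg$nucleus_mask), oracle_disk_area(8))
})

test_that("shape measures match exact pixel-set geometry", {
  # rasterized disk radius 8
  lab <- matrix(0L, 40, 40)
  for (x in -8:8) for (y in -8:8) if (x^2 + y^2 <= 64) lab[20 + x, 20 + y] <- 1L
  rec <- hestage:::region_props(lab)
  expect_gte(rec$form_factor, 0.85)
  expect_lte(rec$form_factor, 1.1)
  expect_lt(rec$eccentricity, 0.2)
  expect_equal(rec$area, oracle_disk_area(8))
  expect_equal(rec$perimeter, oracle_perimeter(lab == 1))
  expect_equal(rec$equiv_diameter, 2 * sqrt(oracle_disk_area(8) / pi))

  # 1 x 30 line: degenerate but well-defined
  line <- matrix(0L, 10, 40); line[5, 6:35] <- 1L
  lr <- hestage:::region_props(line)
  expect_equal(lr$solidity, 1)
  expect_gt(lr$eccentricity, 0.99)
  expect_lt(lr$eccentricity, 1)
  expect_equal(lr$perimeter, 62)
})

test_that("shape statistics agree with brute-force oracles on random blobs", {
  set.seed(21)
  for (trial in 1:60) {
    mask <- random_blob_mask(24, sigma = runif(1, 0.8, 2.5), frac = runif(1, 0.2, 0.5))
    if (!any(mask)) next
    lab <- hestage:::label8(mask)
    props <- hestage:::region_props(lab)
    orc_lab <- oracle_label8(mask)
    expect_equal(nrow(props), max(orc_lab))
    expect_equal(sort(props$area), sort(tabulate(orc_lab[orc_lab > 0])))
    expect_equal(sum(props$perimeter), oracle_perimeter(mask))
    expect_true(all(props$solidity > 0 & props$solidity <= 1))
    expect_true(all(props$eccentricity >= 0 & props$eccentricity < 1))
    expect_true(all(props$form_factor > 0 & props$form_factor <= 1.1))
  }
})

test_that("neighbor measures are exact for two nuclei at distance 40", {
  img <- solid_image(200, 200, pink)
  img <- paint_disk(img, 80, 100, 6, blue)
  img <- paint_disk(img, 120, 100, 6, blue)
  seg <- segment_nuclei(img)
  rec <- measure_nuclei(seg$labels, img, neighbor_radius = 50)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$nn_dist, c(40, 40))
  expect_equal(rec$neighbor_count, c(1, 1))
  rec2 <- measure_nuclei(seg$labels, img, neighbor_radius = 30)
  expect_equal(rec2$neighbor_count, c(0, 0))
})

test_that("the desmoplastic block always has exactly 675 manifest-ordered values", {
  img <- solid_image(96, 96, pink)
  tissue <- matrix(TRUE, 96, 96)
  empty_rec <- measure_nuclei(matrix(0L, 96, 96), img)
  blk <- desmo_features(empty_rec, img, tissue, matrix(FALSE, 96, 96))
  expect_length(blk, 675)
  expect_named(blk, feature_names("desmoplastic"))
  expect_equal(unname(blk["nucleus_count"]), 0)
  expect_true(all(blk[startsWith(names(blk), "nuc_area_hist")] == 0))
  expect_false(anyNA(blk))

  img2 <- paint_disk(img, 48, 48, 7, blue)
  seg <- segment_nuclei(img2)
  rec <- measure_nuclei(seg$labels, img2)
  blk2 <- desmo_features(rec, img2, tissue, seg$nucleus_mask)
  expect_length(blk2, 675)
  expect_equal(unname(blk2["nucleus_count"]), 1)
  expect_equal(sum(blk2[startsWith(names(blk2), "nuc_area_hist")]), 1)
  expect_false(anyNA(blk2))
})

test_that("aggregates are invariant to record order", {
  ph <- generate_phantom(tiny_spec(nucleus_count = 15, seed = 6))
  img <- ph$truth$pre_illumination
  seg <- segment_nuclei(img)
  rec <- measure_nuclei(seg$labels, img)
  tissue <- ph$truth$tissue_mask
  a <- desmo_features(rec, img, tissue, seg$nucleus_mask)
  set.seed(1)
  b <- desmo_features(rec[sample.int(nrow(rec)), ], img, tissue, seg$nucleus_mask)
  expect_equal(a, b)
})

test_that("nucleus count separates dense from sparse phantoms (Monte Carlo AUC)", {
  n_side <- 25
  ds <- generate_dataset(n_side, n_side,
    ta_spec = tiny_spec(nucleus_count = 15, seed = 1),
    t1_spec = tiny_spec(stage = "T1", nucleus_count = 45, seed = 1),
    seed = 17)
  counts <- vapply(seq_len(nrow(ds)), function(i) {
    ph <- phantom_for_row(ds, i)
    max(segment_nuclei(ph$truth$pre_illumination)$labels)
  }, numeric(1))
  auc <- auc_mann_whitney(counts, ds$stage == "T1")
  expect_gt(auc, 0.95)
})
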