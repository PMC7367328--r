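test_that("identical spec and seed give bit-identical phantoms", {
  a <- generate_phantom(tiny_spec(seed = 11, noise_sd = 3,
                                  illumination_gradient = 0.15, vignette = TRUE))
  b <- generate_phantom(tiny_spec(seed = 11, noise_sd = 3,
                                  illumination_gradient = 0.15, vignette = TRUE))
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
})

test_that("fixed nucleus count is honored and masks obey the typed invariants", {
  ph <- generate_phantom(tiny_spec(nucleus_count = 50, count_dist = "fixed",
                                   seed = 5))
  tr <- ph$truth
  expect_equal(nrow(tr$nucleus_centers), 50)
  expect_false(any(tr$crack_mask & tr$gap_mask))
  expect_false(any(tr$crack_mask & tr$tissue_mask))
  expect_true(all(tr$tissue_mask[tr$nucleus_mask]))
  # tissue plus non-tissue covers the tile
  expect_true(all(tr$tissue_mask | tr$crack_mask | tr$gap_mask))
})

test_that("zero crack fraction and zero gaps give empty artifact masks", {
  ph <- generate_phantom(tiny_spec(crack_fraction = 0, gap_count = 0, seed = 2))
  expect_equal(sum(ph$truth$crack_mask), 0)
  expect_equal(sum(ph$truth$gap_mask), 0)
  expect_true(all(ph$truth$tissue_mask))
})

test_that("ground-truth crack components stay strictly below the diameter rule", {
  for (s in 1:3) {
    ph <- generate_phantom(tiny_spec(stage = "T1", crack_fraction = 0.02,
                                     nucleus_count = 30, seed = s))
    cr <- ph$truth$crack_mask
    if (sum(cr) == 0) next
    lab <- oracle_label8(cr)
    areas <- tabulate(lab[lab > 0])
    expect_true(all(2 * sqrt(areas / pi) <= 40))
    # and gaps strictly above
    gl <- oracle_label8(ph$truth$gap_mask)
    gareas <- tabulate(gl[gl > 0])
    expect_true(all(2 * sqrt(gareas / pi) > 40))
  }
})

test_that("pinkness shift moves the cytoplasm red channel by exactly its value", {
  a <- generate_phantom(tiny_spec(seed = 9, pinkness_shift = 0))
  b <- generate_phantom(tiny_spec(seed = 9, pinkness_shift = 20))
  cyto <- a$truth$tissue_mask & !a$truth$nucleus_mask
  ra <- a$truth$pre_illumination[, , 1][cyto]
  rb <- b$truth$pre_illumination[, , 1][cyto]
  expect_equal(mean(rb - ra), 20)
  # monotone: a middling shift sits strictly between
  m <- generate_phantom(tiny_spec(seed = 9, pinkness_shift = 10))
  rm <- m$truth$pre_illumination[, , 1][cyto]
  expect_true(mean(ra) < mean(rm) && mean(rm) < mean(rb))
})

test_that("dataset manifests are labeled, sized, and reproducible", {
  ds <- generate_dataset(3, 5, seed = 7)
  expect_equal(nrow(ds), 8)
  expect_equal(ds$stage, c(rep("Ta", 3), rep("T1", 5)))
  ds2 <- generate_dataset(3, 5, seed = 7)
  expect_identical(ds$seed, ds2$seed)
  expect_identical(phantom_for_row(ds, 4)$image, phantom_for_row(ds2, 4)$image)
})

test_that("doubling crack fraction raises ground-truth crack area (Monte Carlo)", {
  n_side <- 40
  ta <- generate_dataset(n_side, n_side,
    ta_spec = tiny_spec(crack_fraction = 0.01, nucleus_count = 25),
    t1_spec = tiny_spec(stage = "T1", crack_fraction = 0.02, nucleus_count = 25),
    seed = 31)
  crack_px <- vapply(seq_len(nrow(ta)), function(i) {
    sum(phantom_for_row(ta, i)$truth$crack_mask)
  }, numeric(1))
  wt <- stats::wilcox.test(crack_px[ta$stage == "T1"], crack_px[ta$stage == "Ta"],
                           alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("unsatisfiable nucleus packing raises an explicit error", {
  expect_error(
    generate_phantom(phantom_spec(image_size = 64, nucleus_count = 400,
                                  count_dist = "fixed", nucleus_radius_mean = 6,
                                  nucleus_radius_sd = 0.5, gap_count = 0,
                                  seed = 1)),
    "packing"
  )
})

test_that("written datasets round-trip through PNG with manifest", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(1, 1, ta_spec = tiny_spec(), t1_spec = tiny_spec(stage = "T1"),
                         seed = 3)
  write_phantom_dataset(ds, dir, write_masks = FALSE)
  man <- readr::read_csv(file.path(dir, "manifest.csv"), show_col_types = FALSE)
  expect_equal(nrow(man), 2)
  img <- read_rgb_image(file.path(dir, man$filename[1]))
  expect_identical(img, phantom_for_row(ds, 1)$image)
})
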