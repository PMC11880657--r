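test_that("dose renormalization rescales to 2 Gy x 25 fractions", {
  d <- as_dm(array(40, c(4, 4, 2)))
  expect_identical(renormalize_dose(d, 50)$values, d$values * 1) # identity
  expect_equal(renormalize_dose(d, 40)$values[1], 50)            # 40 x 50/40
  d2 <- as_dm(array(42.56, c(2, 2, 2)))
  expect_equal(renormalize_dose(d2, 42.56)$values[1], 50)
  expect_equal(renormalize_dose(d2, 42.56)$technique, d2$technique)
  expect_error(renormalize_dose(d, 0), "positive")
})

test_that("body crop box is the margin-expanded tight bounding box", {
  ct <- matrix(0, 128, 128)
  masks <- list(body = matrix(0, 128, 128))
  masks$body[11:91, 21:60] <- 1
  cr <- crop_to_body(ct, masks, NULL, prep_config(crop_margin = 0))
  expect_identical(unname(cr$crop_box), c(10L, 20L, 91L, 60L)) # 0-based half-open
  expect_identical(dim(cr$masks$body), c(81L, 40L))
  # full-frame body, margin 0 -> full frame
  full <- list(body = matrix(1, 16, 16))
  cr2 <- crop_to_body(matrix(0, 16, 16), full, NULL, prep_config(crop_margin = 0))
  expect_identical(unname(cr2$crop_box), c(0L, 0L, 16L, 16L))
  # margin near the edge is clipped, never out of range
  edge <- list(body = matrix(0, 20, 20)); edge$body[1:4, 17:20] <- 1
  cr3 <- crop_to_body(matrix(0, 20, 20), edge, NULL, prep_config(crop_margin = 5))
  expect_identical(unname(cr3$crop_box), c(0L, 11L, 9L, 20L))
  # empty body -> NULL with warning
  expect_warning(
    out <- crop_to_body(ct, list(body = matrix(0, 4, 4)), NULL, prep_config()),
    "empty body")
  expect_null(out)
  # all three grids are cropped identically
  dose <- matrix(seq_len(128 * 128), 128, 128)
  cr4 <- crop_to_body(dose, masks, dose, prep_config(crop_margin = 2))
  expect_identical(cr4$ct, cr4$dose)
})

test_that("nearest-neighbour resampling matches exhaustive nearest-source search", {
  expect_identical(resample_nn(diag(4), c(4, 4)), diag(4))  # identity
  g <- matrix(c(1, 3, 2, 4), 2, 2)
  up <- resample_nn(g, c(4, 4))
  expect_true(all(up %in% g))                               # value preservation
  set.seed(5)
  for (rep in 1:25) {
    nr <- sample(1:8, 1); nc <- sample(1:8, 1)
    gr <- matrix(rnorm(nr * nc), nr, nc)
    os <- c(sample(1:8, 1), sample(1:8, 1))
    expect_identical(resample_nn(gr, os), brute_resample_nn(gr, os))
  }
  # binary masks remain binary
  m <- matrix(rbinom(36, 1, 0.4), 6, 6)
  expect_true(all(resample_nn(m, c(13, 7)) %in% c(0, 1)))
  expect_error(resample_nn(g, c(0, 4)), "positive")
})

test_that("slice assembly counts, channel order and degenerate channels", {
  spec <- small_spec(1, seed = 55, node_positive_prob = 0)
  case <- generate_case(spec, 1)
  dose <- simulate_dose_3dcrt(case)
  cfg <- prep_config(target_size = c(64, 64))
  slices <- assemble_slices(case, dose, cfg)
  n_body <- sum(vapply(seq_len(dim(case$ct)[3]),
                       function(i) any(case$masks$body[, , i] != 0), logical(1)))
  expect_length(slices, n_body)
  for (s in slices) {
    expect_identical(dim(s$input), c(64L, 64L, 6L))
    expect_identical(dim(s$target), c(64L, 64L))
    # mask channels stay binary after resampling, CT channel in [0,1]
    expect_true(all(s$input[, , 2:6] %in% c(0, 1)))
    expect_true(all(s$input[, , 1] >= 0 & s$input[, , 1] <= 1))
    # node-negative case: nodal channel is identically zero
    expect_equal(sum(s$input[, , 6]), 0)
    expect_true(all(s$target >= 0))
  }
  # misaligned dose grid is rejected
  bad <- dose; bad$values <- bad$values[, , -1, drop = FALSE]
  expect_error(assemble_slices(case, bad, cfg), "aligned")
})

test_that("crop/resample round trip preserves volumetric DVH metrics", {
  case <- fixed_case(heart_proximity = 0.6, seed = 61)
  dose <- simulate_dose_3dcrt(case)
  cfg <- prep_config(target_size = c(128, 128))
  slices <- assemble_slices(case, dose, cfg)
  back <- restore_dose(lapply(slices, `[[`, "target"), slices, case)
  for (st in c("ptv_breast", "heart", "lung_ipsi")) {
    m0 <- extract_metrics(dose, case$masks[[st]], 50, st, case$spacing)
    m1 <- extract_metrics(back, case$masks[[st]], 50, st, case$spacing)
    expect_lt(abs(m0$Dmean - m1$Dmean), 0.02 * case$prescription)
  }
})

test_that("k-fold split partitions patients with near-equal folds, deterministically", {
  ids <- sprintf("case%02d", 1:14)
  plan <- kfold_split(ids, k = 7, seed = 3)
  expect_identical(sort(unique(plan$assignments)), 1:7)
  expect_true(all(tabulate(plan$assignments, 7) == 2))
  # union of test folds covers every case exactly once
  expect_identical(sort(names(plan$assignments)), sort(ids))
  expect_identical(plan$assignments, kfold_split(ids, 7, seed = 3)$assignments)
  expect_false(identical(plan$assignments, kfold_split(ids, 7, seed = 4)$assignments))
  # uneven split sizes differ by at most one
  p2 <- kfold_split(sprintf("c%d", 1:16), k = 7, seed = 1)
  expect_lte(diff(range(tabulate(p2$assignments, 7))), 1)
  expect_error(kfold_split(ids[1:5], k = 7), "k must lie")
})
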