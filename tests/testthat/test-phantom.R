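test_that("case generation is deterministic and leaves the global RNG alone", {
  spec <- small_spec(3, seed = 42)
  set.seed(999); before <- .Random.seed
  a <- generate_case(spec, 2)
  expect_identical(.Random.seed, before)
  b <- generate_case(spec, 2)
  expect_identical(a, b)
  d <- generate_case(spec, 3)
  expect_false(identical(a$ct, d$ct))
})

test_that("generated cases satisfy all structural invariants", {
  for (inst in c("inst1", "inst2")) {
    spec <- small_spec(4, institution = inst, seed = 7)
    for (i in 1:4) {
      case <- generate_case(spec, i)
      expect_true(validate_case(case))
      expect_equal(case$prescription, 50)
      expect_equal(case$spacing[3], if (inst == "inst1") 3.75 else 3.0)
      expect_identical(!is.null(case$masks$ptv_nodes),
                       case$covariates$node_positive)
      expect_true(all(case$masks$body[, , dim(case$ct)[3]] %in% c(0, 1)))
    }
  }
})

test_that("degenerate node probability yields node-negative cases only", {
  spec <- small_spec(5, seed = 13, node_positive_prob = 0)
  for (i in 1:5)
    expect_null(generate_case(spec, i)$masks$ptv_nodes)
  spec1 <- small_spec(5, seed = 13, node_positive_prob = 1)
  for (i in 1:5)
    expect_false(is.null(generate_case(spec1, i)$masks$ptv_nodes))
})

test_that("invalid cohort parameters raise configuration errors naming the field", {
  expect_error(cohort_spec(0, "inst1"), "n_cases")
  expect_error(small_spec(2, heart_proximity_range = c(0.5, 0.1)),
               "heart_proximity_range")
  expect_error(small_spec(2, node_positive_prob = 1.4), "node_positive_prob")
  expect_error(generate_case(small_spec(2), 3), "index")
})

test_that("heart dose under tangents reflects heart-chest-wall geometry", {
  easy <- fixed_case(heart_proximity = 0.05)
  hard <- fixed_case(heart_proximity = 0.95)
  de <- simulate_dose_3dcrt(easy)
  dh <- simulate_dose_3dcrt(hard)
  he <- extract_metrics(de, easy$masks$heart, 50, "heart", easy$spacing)
  hh <- extract_metrics(dh, hard$masks$heart, 50, "heart", hard$spacing)
  expect_lt(he$Dmean, 3)
  expect_gt(hh$Dmean, 3)
  # IMRT spares the heart on the hard geometry
  ih <- extract_metrics(simulate_dose_imrt(hard), hard$masks$heart, 50,
                        "heart", hard$spacing)
  expect_lt(ih$Dmean, hh$Dmean)
  # both techniques meet every constraint on the easy geometry
  mets <- function(case, dm) list(
    lung = extract_metrics(dm, case$masks$lung_ipsi, 50, "lung", case$spacing),
    heart = extract_metrics(dm, case$masks$heart, 50, "heart", case$spacing))
  expect_true(check_constraints(mets(easy, de))$pass)
  expect_true(check_constraints(mets(easy, simulate_dose_imrt(easy)))$pass)
})

test_that("heart mean dose grows monotonically with the proximity covariate", {
  dm <- vapply(seq(0, 1, by = 0.2), function(p) {
    case <- fixed_case(heart_proximity = p, seed = 5)
    d <- simulate_dose_3dcrt(case)
    extract_metrics(d, case$masks$heart, 50, "heart", case$spacing)$Dmean
  }, numeric(1))
  expect_true(all(diff(dm) >= -1e-6))
  expect_gt(dm[6], dm[1])
})

test_that("paired-technique contrasts hold across a cohort sweep", {
  spec <- cohort_spec(12, "inst2", seed = 31, grid_n = 64, pixel_mm = 5,
                      n_slices = 8)
  for (i in 1:12) {
    case <- generate_case(spec, i)
    dc <- simulate_dose_3dcrt(case)
    di <- simulate_dose_imrt(case)
    body <- case$masks$body != 0
    rx <- case$prescription
    # dose maps valid: non-negative, bounded by 1.3 x prescription
    expect_gte(min(dc$values), 0); expect_gte(min(di$values), 0)
    expect_lte(max(dc$values), 1.3 * rx)
    expect_lte(max(di$values), 1.3 * rx)
    # larger low-dose bath under IMRT
    expect_gte(sum(di$values >= 5 & body), sum(dc$values >= 5 & body))
    # equal or lower high-dose OAR spill under IMRT
    hm <- function(d, m) extract_metrics(d, m, rx, "s", case$spacing)
    expect_lte(hm(di, case$masks$heart)$V25Gy, hm(dc, case$masks$heart)$V25Gy)
    expect_lte(hm(di, case$masks$lung_ipsi)$V20Gy,
               hm(dc, case$masks$lung_ipsi)$V20Gy)
    # equal or better PTV homogeneity under IMRT
    pc <- dc$values[case$masks$ptv_breast != 0]
    pi_ <- di$values[case$masks$ptv_breast != 0]
    expect_lte(sd(pi_) / mean(pi_), sd(pc) / mean(pc))
  }
})

test_that("a case with no target volume receives at most a scatter bath", {
  case <- fixed_case(seed = 21)
  case$masks$ptv_breast[] <- 0
  case$masks$ptv_nodes <- NULL
  case$masks$heart[] <- 0
  case$masks$lung_ipsi[] <- 0
  case$masks$lung_contra[] <- 0
  d <- simulate_dose_3dcrt(case)
  expect_lte(max(d$values), 0.05 * case$prescription)
})

test_that("cohort labels come from constraints on simulated dose and are reproducible", {
  spec <- small_spec(4, institution = "inst2", seed = 19)
  cohort <- generate_cohort(spec)
  labels <- vapply(cohort, `[[`, character(1), "label")
  for (e in cohort) {
    m <- list(
      lung = extract_metrics(e$dose_crt, e$case$masks$lung_ipsi, 50, "lung",
                             e$case$spacing),
      heart = extract_metrics(e$dose_crt, e$case$masks$heart, 50, "heart",
                              e$case$spacing))
    expect_identical(e$label,
                     if (check_constraints(m)$pass) "3DCRT" else "IMRT")
  }
  cohort2 <- generate_cohort(spec)
  expect_identical(labels, vapply(cohort2, `[[`, character(1), "label"))
  # all-easy spec: every label is 3DCRT by construction
  easy <- cohort_spec(3, "inst2", seed = 19, grid_n = 64, pixel_mm = 5,
                      n_slices = 8, heart_proximity_range = c(0, 0.05),
                      ptv_size_range = c(0.75, 0.85))
  expect_true(all(vapply(generate_cohort(easy), `[[`, character(1),
                         "label") == "3DCRT"))
})

test_that("default mixed-institution cohorts label roughly three quarters 3D-CRT", {
  # the default inst2 complexity mix emulates a referral population in
  # which about 23 of 30 patients can be treated conformally
  spec <- cohort_spec(60, "inst2", seed = 4242)
  labels <- vapply(generate_cohort(spec), `[[`, character(1), "label")
  expect_lt(abs(mean(labels == "3DCRT") - 23 / 30), 0.15)
})

test_that("cohort persistence writes one container per case plus a manifest", {
  dir <- tempfile("cohort")
  cohort <- generate_cohort(small_spec(2, seed = 3))
  manifest <- write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_equal(nrow(manifest), 2)
  reread <- readRDS(file.path(dir, paste0(cohort[[1]]$case$case_id, ".rds")))
  expect_identical(reread$case$ct, cohort[[1]]$case$ct)
  unlink(dir, recursive = TRUE)
})
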