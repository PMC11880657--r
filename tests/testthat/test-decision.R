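mk_oar <- function(lung_V20 = 25, heart_V25 = 5, heart_Dmean = 2) {
  mk <- function(structure, Dmean = 1, V20 = 0, V25 = 0) structure(
    list(structure = structure, present = TRUE, Dmean = Dmean, D95 = 1,
         V95 = 100, V20Gy = V20, V25Gy = V25, n_voxels = 100L,
         total_volume = 10), class = "dvh_metrics")
  list(lung = mk("lung_ipsi", Dmean = 8, V20 = lung_V20),
       heart = mk("heart", Dmean = heart_Dmean, V25 = heart_V25))
}

test_that("constraint checking is strict and lists every violation", {
  ok <- check_constraints(mk_oar(25, 5, 2))
  expect_true(ok$pass); expect_equal(nrow(ok$violations), 0)
  # exactly at threshold fails: comparisons are strict '<'
  expect_false(check_constraints(mk_oar(lung_V20 = 30))$pass)
  two <- check_constraints(mk_oar(lung_V20 = 35, heart_Dmean = 4))
  expect_false(two$pass)
  expect_setequal(two$violations$constraint, c("lung_V20Gy", "heart_Dmean"))
  expect_equal(two$violations$observed[two$violations$constraint == "lung_V20Gy"], 35)
  # a missing OAR is an error, never a silent pass
  expect_error(check_constraints(list(lung = mk_oar()$lung)), "heart")
  absent <- mk_oar(); absent$heart$present <- FALSE
  expect_error(check_constraints(absent), "heart")
})

test_that("recommendation defaults to 3D-CRT and escalates only on failure", {
  both <- recommend(mk_oar(), mk_oar())
  expect_identical(both$recommended, "3DCRT")
  expect_false(both$needs_review)
  resc <- recommend(mk_oar(lung_V20 = 33), mk_oar())
  expect_identical(resc$recommended, "IMRT")
  expect_false(resc$needs_review)
  expect_true("lung_V20Gy" %in% resc$violations$constraint)
  neither <- recommend(mk_oar(heart_Dmean = 5), mk_oar(heart_Dmean = 4))
  expect_identical(neither$recommended, "IMRT")
  expect_true(neither$needs_review)
  # invariant: 3DCRT recommended iff its plan passes
  expect_identical(both$crt_pass, both$recommended == "3DCRT")
  expect_identical(resc$crt_pass, resc$recommended == "3DCRT")
})

test_that("confusion matrices count decision/truth pairs exactly", {
  gt <- rep(c("3DCRT", "IMRT"), each = 15)
  cm <- build_confusion(gt, gt)
  expect_equal(unname(cm$fp + cm$fn), 0)
  expect_equal(unname(cm$tp), 15); expect_equal(unname(cm$tn), 15)
  # order invariance
  set.seed(2)
  dec <- sample(c("3DCRT", "IMRT"), 30, replace = TRUE)
  p <- sample(30)
  cm1 <- build_confusion(gt, dec); cm2 <- build_confusion(gt[p], dec[p])
  expect_equal(cm1$table, cm2$table)
  expect_error(build_confusion(gt, dec[1:10]), "different case sets")
  expect_error(build_confusion(c("3DCRT", "VMAT"), c("3DCRT", "IMRT")), "labels")
})

test_that("classification metrics match a brute-force recount on random label pairs", {
  set.seed(14)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    gt <- sample(c("3DCRT", "IMRT"), n, replace = TRUE, prob = c(0.7, 0.3))
    dec <- sample(c("3DCRT", "IMRT"), n, replace = TRUE)
    rep_pkg <- classification_report(build_confusion(gt, dec))
    rep_bf <- brute_report(gt, dec)
    expect_equal(rep_pkg$accuracy, rep_bf$accuracy)
    expect_equal(rep_pkg$recall, rep_bf$recall)
    expect_equal(rep_pkg$precision, rep_bf$precision)
  }
  # perfect agreement: all metrics 100
  perfect <- classification_report(confusion_from_counts(20, 0, 0, 10))
  expect_equal(perfect$accuracy, 100); expect_equal(perfect$f1, 100)
  # undefined metrics are NA, never zero
  nop <- classification_report(confusion_from_counts(0, 0, 10, 5))
  expect_true(is.na(nop$precision))
})

test_that("degrading predicted lung dose cannot improve framework accuracy", {
  spec <- cohort_spec(8, "inst2", seed = 23, grid_n = 64, pixel_mm = 5,
                      n_slices = 8)
  cohort <- generate_cohort(spec)
  metrics_for <- function(bias) lapply(cohort, function(e) {
    m <- function(dm, extra = 0) {
      lung <- extract_metrics(dm, e$case$masks$lung_ipsi, 50, "lung",
                              e$case$spacing)
      lung$V20Gy <- min(lung$V20Gy + extra, 100)
      list(lung = lung,
           heart = extract_metrics(dm, e$case$masks$heart, 50, "heart",
                                   e$case$spacing))
    }
    list(case_id = e$case$case_id, crt = m(e$dose_crt, bias),
         imrt = m(e$dose_imrt))
  })
  gt <- vapply(cohort, `[[`, character(1), "label")
  oracle <- run_framework(metrics_for(0), gt)
  degraded <- run_framework(metrics_for(10), gt)
  expect_equal(oracle$report$accuracy, 100)
  expect_lte(degraded$report$accuracy, oracle$report$accuracy)
  # audit rows trace every decision
  expect_identical(nrow(oracle$audit), length(cohort))
  expect_true(all(oracle$audit$recommended == gt))
})
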