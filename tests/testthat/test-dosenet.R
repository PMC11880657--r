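# shared small training setup: one phantom, 3D-CRT dose, 64x64 slices
prep64 <- prep_config(target_size = c(64, 64))
net_cfg <- dosenet_config(input_channels = 6, base_filters = 16, depth = 3)

test_that("weight initialization is deterministic given the seed", {
  p1 <- dosenet_init(net_cfg, seed = 11)
  p2 <- dosenet_init(net_cfg, seed = 11)
  expect_identical(p1, p2)
  expect_false(identical(p1, dosenet_init(net_cfg, seed = 12)))
  expect_gt(length(p1), 1e4)
})

test_that("an untrained network maps 64x64xC input to a finite 64x64 dose slice", {
  m0 <- dosenet(list(x = array(0.5, c(64, 64, 6, 1)),
                     y = array(0, c(64, 64, 1))),
                net_cfg, dosenet_control(epochs = 0, seed = 1))
  set.seed(9)
  x <- array(runif(64 * 64 * 6 * 2), c(64, 64, 6, 2))
  pred <- predict(m0, x)
  expect_identical(dim(pred), c(64L, 64L, 2L))
  expect_true(all(is.finite(pred)))
  expect_true(all(pred >= 0))  # non-negative dose head
})

test_that("input contracts are enforced", {
  expect_error(dosenet(list(), net_cfg), "empty")
  expect_error(
    dosenet(list(x = array(0, c(64, 64, 4, 1)), y = array(0, c(64, 64, 1))),
            net_cfg), "channel")
  expect_error(
    dosenet(list(x = array(0, c(62, 62, 6, 1)), y = array(0, c(62, 62, 1))),
            net_cfg), "divisible")
  expect_error(dosenet_config(depth = 1), "depth")
  expect_error(dosenet_config(base_filters = 4), "base_filters")
})

test_that("training overfits a single slice and descends on a small cohort", {
  case <- fixed_case(heart_proximity = 0.4, seed = 31)
  dose <- simulate_dose_3dcrt(case)
  slices <- assemble_slices(case, dose, prep64)
  # overfit-one-sample oracle: 200 epochs drive MSE below 1% of initial
  one <- slices[5]
  m1 <- dosenet(one, net_cfg, dosenet_control(epochs = 200, batch_size = 1,
                                              seed = 4))
  expect_lt(m1$loss[200], 0.01 * m1$loss[1])
  # multi-case descent: final epoch training loss below the first
  cohort <- generate_cohort(small_spec(4, seed = 71))
  tr <- do.call(c, lapply(cohort, function(e)
    assemble_slices(e$case, e$dose_crt, prep64)))
  m <- dosenet(tr, net_cfg, dosenet_control(epochs = 5, seed = 2))
  expect_length(m$loss, 5)
  expect_lt(m$loss[5], m$loss[1])
  expect_true(all(is.finite(m$loss)))
})

test_that("fine-tuning starts exactly from the supplied weights", {
  case <- fixed_case(seed = 41)
  dose <- simulate_dose_3dcrt(case)
  slices <- assemble_slices(case, dose, prep64)
  src <- dosenet(slices, net_cfg, dosenet_control(epochs = 2, seed = 6))
  # zero gradient steps: predictions identical to the source model
  ft0 <- dosenet(slices, net_cfg, dosenet_control(epochs = 0, seed = 99),
                 init = src)
  expect_identical(ft0$par, src$par)
  expect_identical(ft0$mode, "fine_tune")
  expect_equal(predict(ft0, slices), predict(src, slices))
  expect_error(dosenet(slices, dosenet_config(6, 16, 4),
                       dosenet_control(epochs = 0), init = src),
               "initial weights")
})

test_that("cross-validation trains per fold without leakage and predicts each case once", {
  cohort <- generate_cohort(small_spec(4, seed = 81))
  ctl <- dosenet_control(epochs = 1, seed = 5)
  cv <- run_cross_validation(cohort, "3DCRT", k = 2, prep = prep64,
                             config = net_cfg, control = ctl,
                             regime_name = "ModelA")
  expect_length(cv$models, 2)
  expect_length(cv$predictions, 4)
  ids <- vapply(cohort, function(e) e$case$case_id, character(1))
  expect_setequal(names(cv$predictions), ids)
  for (id in ids)
    expect_identical(dim(cv$predictions[[id]]$values),
                     dim(cohort[[match(id, ids)]]$case$ct))
  # regime initialization contracts
  expect_error(run_cross_validation(cohort, "IMRT", k = 2, prep = prep64,
                                    config = net_cfg, control = ctl,
                                    regime_name = "ModelC"),
               "supply init")
  expect_error(run_cross_validation(cohort, "IMRT", k = 2, prep = prep64,
                                    config = net_cfg, control = ctl,
                                    init = cv$models[[1]],
                                    regime_name = "ModelD"),
               "from scratch")
})

test_that("case prediction respects the body mask and grid alignment", {
  case <- fixed_case(seed = 51)
  dose <- simulate_dose_3dcrt(case)
  m <- dosenet(assemble_slices(case, dose, prep64), net_cfg,
               dosenet_control(epochs = 2, seed = 3))
  pred <- predict_case(m, case, prep64)
  expect_identical(dim(pred$values), dim(case$ct))
  expect_true(all(pred$values[case$masks$body == 0] == 0))
  expect_gte(min(pred$values), 0)
})
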