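#' U-Net architecture configuration
#'
#' Describes the 2D U-Net dose regressor: an encoder–decoder with skip
#' connections, optionally with Xception-style depthwise-separable
#' convolutions in the encoder blocks, and a 1x1-convolution + ReLU head
#' so the predicted dose map is non-negative. The input spatial size must
#' be divisible by `2^(depth - 1)`.
#'
#' @param input_channels number of input channels (default 6: normalized
#'   CT plus the five structure masks).
#' @param base_filters filters at the first resolution level (>= 8);
#'   doubled at each downsampling.
#' @param depth number of resolution levels including the bottleneck
#'   (>= 2).
#' @param separable use depthwise-separable convolutions in the encoder
#'   blocks (bottleneck and decoder use full 3x3 convolutions).
#' @return a `dosenet_config`.
#' @export
dosenet_config <- function(input_channels = 6, base_filters = 32,
                           depth = 4, separable = TRUE) {
  if (depth < 2) stop("depth must be >= 2")
  if (base_filters < 8) stop("base_filters must be >= 8")
  if (input_channels < 1) stop("input_channels must be >= 1")
  structure(list(input_channels = as.integer(input_channels),
                 base_filters = as.integer(base_filters),
                 depth = as.integer(depth),
                 separable = isTRUE(separable)),
            class = "dosenet_config")
}

as_cfg_vec <- function(config) {
  c(config$input_channels, config$depth, config$base_filters,
    as.integer(config$separable))
}

#' Training-control parameters
#'
#' Training uses voxel-wise mean-squared error on absolute dose and the
#' Adam optimizer with learning rate 0.001, beta1 = 0.9, beta2 = 0.999,
#' for 20 epochs — no validation split or early stopping. `epochs = 0` is
#' allowed as an inspection override (the returned model carries its
#' initial weights unchanged, useful for verifying fine-tuning
#' initialization).
#'
#' @param epochs number of epochs (>= 0).
#' @param learning_rate,beta1,beta2 Adam parameters.
#' @param batch_size mini-batch size (default 16).
#' @param seed integer seed for weight initialization and shuffling.
#' @return a `dosenet_control`.
#' @export
dosenet_control <- function(epochs = 20, learning_rate = 0.001,
                            beta1 = 0.9, beta2 = 0.999,
                            batch_size = 16, seed = 1) {
  if (epochs < 0) stop("epochs must be >= 0")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (batch_size < 1) stop("batch_size must be >= 1")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "dosenet_control")
}

# internal: stack a list of training slices into (H,W,C,N) / (H,W,N)
stack_slices <- function(slices, need_target = TRUE) {
  if (length(slices) == 0) stop("the training set is empty")
  d <- dim(slices[[1]]$input)
  x <- array(0, c(d[1], d[2], d[3], length(slices)))
  y <- if (need_target) array(0, c(d[1], d[2], length(slices)))
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    if (!identical(dim(s$input), d)) stop("slices have inconsistent shapes")
    x[, , , i] <- s$input
    if (need_target) {
      if (is.null(s$target)) stop("slice has no dose target")
      y[, , i] <- s$target
    }
  }
  list(x = x, y = y)
}

#' Initial network weights
#'
#' He-normal initialization (`sd = sqrt(2 / fan_in)`) for all convolution
#' weights, zero biases; deterministic given the seed.
#'
#' @param config a [dosenet_config()].
#' @param seed integer seed.
#' @return numeric parameter vector.
#' @export
dosenet_init <- function(config, seed = 1) {
  info <- unet_param_info_cpp(as_cfg_vec(config))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  par <- numeric(info$n_params)
  tt <- info$tensors
  for (i in seq_len(nrow(tt))) {
    idx <- tt$offset[i] + seq_len(tt$length[i]) - 1
    par[idx] <- if (tt$fan_in[i] > 0)
      stats::rnorm(tt$length[i], 0, sqrt(2 / tt$fan_in[i])) else 0
  }
  par
}

#' Fit the 2D U-Net dose regressor
#'
#' Trains the network to map per-slice CT + structure-mask channels to
#' the 2D absolute dose map, by mini-batch Adam on voxel-wise MSE.
#' Supply `init` (a fitted `dosenet` or its coefficient vector) to
#' fine-tune: all layers stay trainable; only the starting point changes.
#'
#' @param x list of training slices from [assemble_slices()], or a list
#'   with elements `x` (H x W x C x N input array) and `y` (H x W x N
#'   dose array).
#' @param config a [dosenet_config()].
#' @param control a [dosenet_control()].
#' @param init `NULL` for random (from-scratch) initialization, or a
#'   `dosenet` / numeric parameter vector to fine-tune from.
#' @return a `dosenet` object with components `par` (trained weights),
#'   `loss` (per-epoch training MSE in Gy^2), `config`, `control`,
#'   `n_slices`, `mode` (`"from_scratch"`/`"fine_tune"`).
#' @export
dosenet <- function(x, config = dosenet_config(),
                    control = dosenet_control(), init = NULL) {
  cl <- match.call()
  data <- if (is.list(x) && !is.null(x$x)) x else stack_slices(x)
  d <- dim(data$x)
  if (d[3] != config$input_channels)
    stop("input channel count does not match the model configuration")
  if (any(d[1:2] %% 2^(config$depth - 1) != 0))
    stop("spatial size must be divisible by 2^(depth - 1)")
  mode <- if (is.null(init)) "from_scratch" else "fine_tune"
  par0 <- if (is.null(init)) dosenet_init(config, control$seed)
    else if (inherits(init, "dosenet")) init$par else as.numeric(init)
  info <- unet_param_info_cpp(as_cfg_vec(config))
  if (length(par0) != info$n_params)
    stop("initial weights do not match the model configuration")
  n <- d[4]
  if (control$epochs == 0L) {
    par <- par0; loss <- numeric(0)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(control$seed + 1L)
    ord <- matrix(0L, control$epochs, n)
    for (e in seq_len(control$epochs)) ord[e, ] <- sample.int(n) - 1L
    fit <- unet_train_cpp(par0, data$x, data$y, as_cfg_vec(config),
                          control[c("epochs", "learning_rate", "beta1",
                                    "beta2", "batch_size")], ord)
    par <- fit$par; loss <- fit$loss
  }
  structure(list(par = par, loss = loss, config = config, control = control,
                 n_slices = n, input_dim = d[1:3], mode = mode, call = cl),
            class = "dosenet")
}

#' @export
print.dosenet <- function(x, ...) {
  cat(sprintf("2D U-Net dose regressor (%s)\n", x$mode))
  cat(sprintf("  depth %d, base filters %d, %s encoder, %d input channels, %s parameters\n",
              x$config$depth, x$config$base_filters,
              if (x$config$separable) "separable" else "full-convolution",
              x$config$input_channels,
              format(length(x$par), big.mark = ",")))
  cat(sprintf("  trained %d epochs on %d slices (%dx%d)\n",
              length(x$loss), x$n_slices, x$input_dim[1], x$input_dim[2]))
  if (length(x$loss))
    cat(sprintf("  training MSE: %.3f -> %.3f Gy^2\n",
                x$loss[1], x$loss[length(x$loss)]))
  invisible(x)
}

#' @export
summary.dosenet <- function(object, ...) {
  info <- unet_param_info_cpp(as_cfg_vec(object$config))
  out <- list(model = object, tensors = info$tensors)
  class(out) <- "summary.dosenet"
  out
}

#' @export
print.summary.dosenet <- function(x, ...) {
  print(x$model)
  cat("\nParameter tensors:\n")
  print(x$tensors, row.names = FALSE)
  invisible(x)
}

#' @export
coef.dosenet <- function(object, ...) object$par

#' @export
plot.dosenet <- function(x, ...) {
  if (!length(x$loss)) {
    warning("model has no training history")
    return(invisible(x))
  }
  graphics::plot(seq_along(x$loss), x$loss, type = "b", pch = 19,
                 xlab = "epoch", ylab = "training MSE (Gy^2)",
                 main = "U-Net training loss", ...)
  invisible(x)
}

#' Predict per-slice dose maps
#'
#' @param object a fitted [dosenet()].
#' @param newdata list of training slices (only `input` is used) or an
#'   H x W x C x N input array.
#' @param ... unused.
#' @return H x W x N array of predicted dose in Gy (non-negative by
#'   construction of the output head).
#' @export
predict.dosenet <- function(object, newdata, ...) {
  x <- if (is.array(newdata)) newdata
    else if (is.list(newdata) && !is.null(newdata$x)) newdata$x
    else stack_slices(newdata, need_target = FALSE)$x
  if (length(dim(x)) == 3) x <- array(x, c(dim(x), 1))
  unet_forward_cpp(object$par, x, as_cfg_vec(object$config))
}

#' Predict a volumetric dose map for a case
#'
#' Runs the slice pipeline end-to-end: assembles network inputs with the
#' stored crop/resample metadata, predicts each axial slice, and maps
#' predictions back to the case grid ([restore_dose()]): voxels outside
#' the body are zero and negative raw outputs are clamped.
#'
#' @param model a fitted [dosenet()].
#' @param case a [patient_case][generate_case].
#' @param config the [prep_config()] used at training time.
#' @param technique technique tag for the returned map.
#' @return a [dose_map] on the case grid.
#' @export
predict_case <- function(model, case, config = prep_config(),
                         technique = c("3DCRT", "IMRT")) {
  technique <- match.arg(technique)
  slices <- assemble_slices(case, dose = NULL, config = config)
  if (!length(slices)) stop("case has no slices with a nonempty body mask")
  preds <- predict(model, slices)
  pred_list <- lapply(seq_len(dim(preds)[3]), function(i) preds[, , i])
  restore_dose(pred_list, slices, case, technique)
}

#' Patient-level cross-validated training and out-of-fold prediction
#'
#' Trains one model per fold on the out-of-fold cases' slices and
#' predicts each held-out case exactly once, mirroring sequential k-fold
#' validation. Fold membership is per patient, never per slice; a case
#' appearing on both sides of a fold is a hard error. Regimes initialized
#' from a source model (`ModelB`, `ModelC`) must supply `init`; regimes
#' trained from scratch (`ModelA`, `ModelD`) must not.
#'
#' @param cohort a [generate_cohort()] result (or any list of entries
#'   with `case` and dose maps).
#' @param technique which reference dose to train on (`"3DCRT"` or
#'   `"IMRT"`).
#' @param k number of folds.
#' @param prep a [prep_config()].
#' @param config a [dosenet_config()].
#' @param control a [dosenet_control()].
#' @param init source weights for fine-tuning regimes (a `dosenet` or
#'   parameter vector), or `NULL`.
#' @param regime_name optional regime tag (`"ModelA"`..`"ModelD"`)
#'   recorded in the result; `ModelB`/`ModelC` require `init`,
#'   `ModelA`/`ModelD` forbid it.
#' @return a `dosenet_cv`: `fold_plan`, `models` (per fold),
#'   `predictions` (named per case: predicted [dose_map]), `reference`
#'   (named per case: the reference [dose_map]), `technique`,
#'   `regime_name`.
#' @export
run_cross_validation <- function(cohort, technique = c("3DCRT", "IMRT"),
                                 k = 7, prep = prep_config(),
                                 config = dosenet_config(),
                                 control = dosenet_control(),
                                 init = NULL, regime_name = NULL) {
  technique <- match.arg(technique)
  if (!is.null(regime_name)) {
    if (regime_name %in% c("ModelB", "ModelC") && is.null(init))
      stop(sprintf("%s fine-tunes from source weights; supply init", regime_name))
    if (regime_name %in% c("ModelA", "ModelD") && !is.null(init))
      stop(sprintf("%s trains from scratch; init must be NULL", regime_name))
  }
  field <- if (technique == "3DCRT") "dose_crt" else "dose_imrt"
  ids <- vapply(cohort, function(e) e$case$case_id, character(1))
  plan <- kfold_split(ids, k, control$seed)
  slices_by_case <- lapply(cohort, function(e)
    assemble_slices(e$case, e[[field]], prep))
  names(slices_by_case) <- ids
  models <- vector("list", k)
  predictions <- list(); reference <- list()
  for (fold in seq_len(k)) {
    test_ids <- names(plan$assignments)[plan$assignments == fold]
    train_ids <- setdiff(ids, test_ids)
    if (length(intersect(train_ids, test_ids)) > 0)
      stop("fold leakage detected: case present in both train and test")
    train_slices <- do.call(c, unname(slices_by_case[train_ids]))
    fold_control <- control
    fold_control$seed <- control$seed + fold
    models[[fold]] <- dosenet(train_slices, config, fold_control, init = init)
    for (id in test_ids) {
      e <- cohort[[match(id, ids)]]
      predictions[[id]] <- predict_case(models[[fold]], e$case, prep,
                                        technique)
      reference[[id]] <- e[[field]]
    }
  }
  if (!setequal(names(predictions), ids) || length(predictions) != length(ids))
    stop("cross-validation did not produce exactly one prediction per case")
  structure(list(fold_plan = plan, models = models,
                 predictions = predictions[ids], reference = reference[ids],
                 technique = technique, regime_name = regime_name,
                 prep = prep), class = "dosenet_cv")
}

#' @export
print.dosenet_cv <- function(x, ...) {
  cat(sprintf("<dosenet_cv> %s%s: %d folds, %d out-of-fold predictions\n",
              x$technique,
              if (!is.null(x$regime_name)) paste0(" (", x$regime_name, ")") else "",
              x$fold_plan$k, length(x$predictions)))
  invisible(x)
}

#' Out-of-fold isodose DSC summary of a cross-validation run
#'
#' Computes the [dsc_curve()] of every out-of-fold prediction against its
#' reference dose and the per-case mean DSC over a threshold band.
#'
#' @param cv a [run_cross_validation()] result.
#' @param thresholds thresholds in percent of prescription.
#' @param band length-2 band in percent for the summary mean.
#' @return list with `curves` (row-bound data.frame) and `band_mean`
#'   (named per-case mean DSC over the band).
#' @export
cv_dsc_summary <- function(cv, thresholds = seq(5, 100, by = 5),
                           band = c(30, 70)) {
  stopifnot(inherits(cv, "dosenet_cv"))
  ids <- names(cv$predictions)
  curves <- do.call(rbind, lapply(ids, function(id)
    dsc_curve(cv$reference[[id]], cv$predictions[[id]],
              cv$reference[[id]]$prescription, thresholds,
              case_id = id, regime = cv$regime_name)))
  band_mean <- vapply(ids, function(id) {
    cur <- curves[curves$case_id == id, ]
    mean_band_dsc(cur, band[1], band[2])
  }, numeric(1))
  list(curves = curves, band_mean = band_mean)
}
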