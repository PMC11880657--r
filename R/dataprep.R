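#' Data-preparation configuration
#'
#' Controls the slice preparation pipeline: body-fitting crop (tight
#' bounding box of the body mask plus margin), nearest-neighbour
#' resampling to a fixed square size, and CT intensity normalization by
#' window/level to `[0, 1]`. Aspect ratio is deliberately not preserved:
#' cropped boxes of varying shape are stretched to the target square, and
#' the crop box plus original shape are stored on every slice so
#' predictions can be mapped back to the original grid for volumetric
#' DVH evaluation.
#'
#' @param target_size integer length-2 output size in pixels (default
#'   `c(128, 128)`).
#' @param crop_margin margin in voxels added around the body bounding box.
#' @param ct_window,ct_level CT normalization window/level in HU
#'   (defaults 400/40): intensities are mapped linearly so that
#'   `level - window/2 -> 0` and `level + window/2 -> 1`, then clamped.
#' @return a `prep_config`.
#' @export
prep_config <- function(target_size = c(128, 128), crop_margin = 2,
                        ct_window = 400, ct_level = 40) {
  if (length(target_size) != 2 || any(target_size <= 0))
    stop("target_size must be two positive integers")
  if (crop_margin < 0) stop("crop_margin must be >= 0")
  if (ct_window <= 0) stop("ct_window must be positive")
  structure(list(target_size = as.integer(target_size),
                 crop_margin = as.integer(crop_margin),
                 ct_window = ct_window, ct_level = ct_level,
                 resample_method = "nearest-neighbor"),
            class = "prep_config")
}

# fixed channel order of the network input
.channel_order <- c("body", "lung_ipsi", "heart", "ptv_breast", "ptv_nodes")

#' Renormalize a dose map to the reference prescription
#'
#' Rescales all voxel doses by `50 / original_prescription` so every plan
#' is expressed at 2 Gy x 25 fractions = 50 Gy, regardless of the dose it
#' was originally prescribed at.
#'
#' @param dose a [dose_map].
#' @param original_prescription the prescription the plan was computed
#'   for, in Gy (> 0).
#' @param target target prescription in Gy (default 50).
#' @return a [dose_map] with rescaled values; grid and technique
#'   unchanged.
#' @export
renormalize_dose <- function(dose, original_prescription, target = 50) {
  stopifnot(inherits(dose, "dose_map"))
  if (original_prescription <= 0)
    stop("original prescription must be positive")
  dose$values <- dose$values * (target / original_prescription)
  dose$prescription <- target
  dose
}

#' Crop a slice triplet to the body bounding box
#'
#' The crop box is the tight bounding box of the body mask, expanded by
#' `crop_margin` voxels and clipped to the image; CT, all masks and the
#' dose are cropped identically. Boxes are 0-based and half-open:
#' `(r0, c0, r1, c1)` selects rows `r0..r1-1` and columns `c0..c1-1`.
#'
#' @param ct_slice 2D CT matrix.
#' @param slice_masks named list of binary matrices (must contain `body`).
#' @param dose_slice 2D dose matrix or `NULL`.
#' @param config a [prep_config()].
#' @return list with `ct`, `masks`, `dose`, `crop_box`,
#'   `original_shape`; or `NULL` (with a warning) when the body mask is
#'   empty on the slice.
#' @export
crop_to_body <- function(ct_slice, slice_masks, dose_slice = NULL,
                         config = prep_config()) {
  body <- slice_masks$body
  if (is.null(body)) stop("slice_masks must contain a 'body' mask")
  if (!any(body != 0)) {
    warning("empty body mask on slice; slice skipped")
    return(NULL)
  }
  rows <- which(rowSums(body != 0) > 0)
  cols <- which(colSums(body != 0) > 0)
  m <- config$crop_margin
  r0 <- max(min(rows) - 1L - m, 0L); r1 <- min(max(rows) + m, nrow(body))
  c0 <- max(min(cols) - 1L - m, 0L); c1 <- min(max(cols) + m, ncol(body))
  take <- function(g) g[(r0 + 1L):r1, (c0 + 1L):c1, drop = FALSE]
  list(ct = take(ct_slice),
       masks = lapply(slice_masks, take),
       dose = if (!is.null(dose_slice)) take(dose_slice),
       crop_box = c(r0 = r0, c0 = c0, r1 = r1, c1 = c1),
       original_shape = dim(body))
}

#' Nearest-neighbour resampling of a 2D grid
#'
#' Output pixel `(i, j)` (0-based) copies the source pixel
#' `(floor((i + 0.5) * nrow_in / nrow_out), floor((j + 0.5) * ncol_in /
#' ncol_out))` — the source pixel whose centre is nearest to the output
#' pixel centre under pixel-centre alignment; when an output centre falls
#' exactly between two source centres the larger source index wins. No
#' interpolation: every
#' output value is an exact copy of an input value, so binary masks stay
#' binary.
#'
#' @param grid 2D numeric matrix.
#' @param out_size integer length-2 `(rows, cols)`.
#' @return matrix of size `out_size`.
#' @export
resample_nn <- function(grid, out_size) {
  if (length(dim(grid)) != 2 || any(dim(grid) == 0)) stop("grid must be a nonempty matrix")
  if (length(out_size) != 2 || any(out_size <= 0))
    stop("out_size must be two positive integers")
  nr <- nrow(grid); nc <- ncol(grid)
  ri <- pmin(floor((seq_len(out_size[1]) - 0.5) * nr / out_size[1]), nr - 1L) + 1L
  ci <- pmin(floor((seq_len(out_size[2]) - 0.5) * nc / out_size[2]), nc - 1L) + 1L
  grid[ri, ci, drop = FALSE]
}

# internal: normalize CT intensities to [0,1] by window/level
normalize_ct <- function(ct, config) {
  lo <- config$ct_level - config$ct_window / 2
  pmin(pmax((ct - lo) / config$ct_window, 0), 1)
}

#' Assemble network-ready training slices from a case
#'
#' Produces one training slice per axial slice with a nonempty body mask:
#' the cropped, resampled and stacked input channels (normalized CT plus
#' one binary channel per structure in the fixed order body,
#' ipsilateral lung, heart, breast PTV, nodal PTV), the matching dose
#' target in Gy, and the crop metadata needed to map predictions back to
#' the original grid. Node-negative cases get an all-zero nodal channel
#' so the channel count is constant.
#'
#' @param case a [patient_case][generate_case].
#' @param dose a [dose_map] aligned to the case grid, or `NULL` when
#'   assembling inputs for prediction only.
#' @param config a [prep_config()].
#' @return list of training slices; each has `input`
#'   (rows x cols x 6 array), `target` (matrix in Gy or `NULL`),
#'   `case_id`, `slice_index`, `crop_box`, `original_shape`.
#' @export
assemble_slices <- function(case, dose = NULL, config = prep_config()) {
  if (!is.null(dose)) {
    stopifnot(inherits(dose, "dose_map"))
    check_aligned(dose, case)
  }
  nz <- dim(case$ct)[3]
  ts <- config$target_size
  out <- list()
  for (iz in seq_len(nz)) {
    sl_masks <- lapply(case$masks, function(m) m[, , iz])
    cr <- withCallingHandlers(
      crop_to_body(case$ct[, , iz], sl_masks,
                   if (!is.null(dose)) dose$values[, , iz], config),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(cr)) next
    chans <- array(0, c(ts[1], ts[2], 1 + length(.channel_order)))
    chans[, , 1] <- resample_nn(normalize_ct(cr$ct, config), ts)
    for (k in seq_along(.channel_order)) {
      nm <- .channel_order[k]
      if (!is.null(cr$masks[[nm]]))
        chans[, , k + 1] <- resample_nn(cr$masks[[nm]], ts)
    }
    out[[length(out) + 1L]] <- list(
      input = chans,
      target = if (!is.null(cr$dose)) resample_nn(cr$dose, ts),
      case_id = case$case_id, slice_index = iz,
      crop_box = cr$crop_box, original_shape = cr$original_shape)
  }
  out
}

#' Map per-slice predictions back to the case grid
#'
#' Inverts the crop/resample pipeline: each predicted slice is
#' nearest-neighbour resampled back to its crop-box shape, pasted into
#' the original slice frame at the stored box, masked to the body and
#' clamped at zero. Slices that were skipped (empty body) stay zero.
#'
#' @param predictions list of predicted 2D matrices, one per element of
#'   `slices`.
#' @param slices the training-slice list the predictions correspond to
#'   (provides `slice_index`, `crop_box`, `original_shape`).
#' @param case the owning [patient_case][generate_case].
#' @param technique technique tag for the returned [dose_map].
#' @return a [dose_map] on the case grid.
#' @export
restore_dose <- function(predictions, slices, case,
                         technique = c("3DCRT", "IMRT")) {
  technique <- match.arg(technique)
  if (length(predictions) != length(slices))
    stop("predictions and slices differ in length")
  vals <- array(0, dim(case$ct))
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    if (is.null(s$crop_box)) stop("slice is missing crop metadata")
    b <- s$crop_box
    sub <- resample_nn(predictions[[i]], c(b["r1"] - b["r0"], b["c1"] - b["c0"]))
    frame <- matrix(0, s$original_shape[1], s$original_shape[2])
    frame[(b["r0"] + 1):b["r1"], (b["c0"] + 1):b["c1"]] <- sub
    vals[, , s$slice_index] <- pmax(frame, 0) * (case$masks$body[, , s$slice_index] != 0)
  }
  dose_map(vals, case$spacing, technique, case$case_id, case$prescription)
}

#' Patient-level k-fold split
#'
#' Assigns whole cases to k folds (all slices of a case share its fold,
#' so no patient contributes slices to both sides of any fold). Folds
#' partition the case set and their sizes differ by at most one;
#' deterministic given the seed.
#'
#' @param case_ids character vector of case identifiers.
#' @param k number of folds (default 7).
#' @param seed integer seed.
#' @return a `fold_plan`: list with `k`, `assignments` (named integer
#'   vector case_id -> fold) and `seed`.
#' @export
kfold_split <- function(case_ids, k = 7, seed = 1) {
  case_ids <- as.character(case_ids)
  if (anyDuplicated(case_ids)) stop("case_ids must be unique")
  if (k < 1 || k > length(case_ids))
    stop("k must lie in [1, number of cases]")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  shuffled <- sample(case_ids)
  folds <- rep(seq_len(k), length.out = length(case_ids))
  assignments <- stats::setNames(folds, shuffled)[case_ids]
  structure(list(k = as.integer(k), assignments = assignments,
                 seed = as.integer(seed)), class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> k = %d over %d cases (seed %d); fold sizes: %s\n",
              x$k, length(x$assignments), x$seed,
              paste(tabulate(x$assignments, x$k), collapse = ", ")))
  invisible(x)
}
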