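#' Isodose volume
#'
#' Binary superlevel set of a dose distribution: voxels receiving at least
#' `threshold_pct` percent of the prescription dose.
#'
#' @param dose a [dose_map] or numeric array in Gy.
#' @param threshold_pct threshold in percent of prescription (0-100).
#' @param prescription prescription dose in Gy.
#' @return integer array of 0/1 with the shape of `dose`.
#' @export
isodose_volume <- function(dose, threshold_pct, prescription = 50) {
  vals <- if (inherits(dose, "dose_map")) dose$values else dose
  if (prescription <= 0) stop("prescription must be positive")
  if (threshold_pct < 0 || threshold_pct > 100)
    stop("threshold_pct must lie in [0, 100]")
  out <- array(0L, dim(vals))
  out[vals >= threshold_pct / 100 * prescription] <- 1L
  out
}

#' Dice similarity coefficient
#'
#' `2|A intersect B| / (|A| + |B|)` for two binary grids of identical shape.
#' When both grids are empty the coefficient is defined as 1 (perfect
#' agreement on absence), which arises at thresholds neither dose reaches.
#'
#' @param a,b binary arrays of identical shape.
#' @return a number in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("grids must have identical shape")
  na <- sum(a != 0); nb <- sum(b != 0)
  if (na + nb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (na + nb)
}

#' Isodose DSC curve between two dose distributions
#'
#' For each threshold (percent of prescription), compares the isodose
#' volumes of the reference and predicted dose with the Dice similarity
#' coefficient. DSC is computed volumetrically per case.
#'
#' @param clinical,predicted aligned [dose_map]s or arrays in Gy.
#' @param prescription prescription dose in Gy.
#' @param thresholds thresholds in percent (default 5, 10, ..., 100).
#' @param case_id,regime labels carried into the result.
#' @return data.frame with `threshold_pct`, `dsc`, `case_id`, `regime`.
#' @export
dsc_curve <- function(clinical, predicted, prescription = 50,
                      thresholds = seq(5, 100, by = 5),
                      case_id = "case", regime = NA_character_) {
  cv <- if (inherits(clinical, "dose_map")) clinical$values else clinical
  pv <- if (inherits(predicted, "dose_map")) predicted$values else predicted
  if (!identical(dim(cv), dim(pv))) stop("dose grids are not aligned")
  vals <- vapply(thresholds, function(t)
    dsc(isodose_volume(cv, t, prescription),
        isodose_volume(pv, t, prescription)), numeric(1))
  data.frame(threshold_pct = thresholds, dsc = vals,
             case_id = case_id, regime = regime)
}

#' Mean DSC over a threshold band
#'
#' Convenience summary of a [dsc_curve()]: the mean DSC over thresholds in
#' `[lo, hi]` percent (default the 30-70% band).
#'
#' @param curve data.frame from [dsc_curve()].
#' @param lo,hi band limits in percent.
#' @return a number.
#' @export
mean_band_dsc <- function(curve, lo = 30, hi = 70) {
  sel <- curve$threshold_pct >= lo & curve$threshold_pct <= hi
  if (!any(sel)) stop("no thresholds inside the requested band")
  mean(curve$dsc[sel])
}

#' Voxelwise dose-difference map
#'
#' Signed `clinical - predicted` difference restricted to the body, with
#' summary statistics over body voxels. Voxels outside the body are set to
#' zero and do not contribute to the summaries.
#'
#' @param clinical,predicted aligned [dose_map]s or arrays in Gy.
#' @param body binary body mask of the same shape.
#' @return list with `difference` (signed array), `mean_difference`,
#'   `mean_abs_difference` and `max_abs_difference` (Gy, over body voxels).
#' @export
dose_difference_map <- function(clinical, predicted, body) {
  cv <- if (inherits(clinical, "dose_map")) clinical$values else clinical
  pv <- if (inherits(predicted, "dose_map")) predicted$values else predicted
  if (!identical(dim(cv), dim(pv)) || !identical(dim(cv), dim(body)))
    stop("dose and body grids are not aligned")
  diff <- (cv - pv) * (body != 0)
  inside <- diff[body != 0]
  list(difference = diff,
       mean_difference = mean(inside),
       mean_abs_difference = mean(abs(inside)),
       max_abs_difference = max(abs(inside)))
}
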