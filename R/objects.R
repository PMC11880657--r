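#' Dose map container
#'
#' A `dose_map` holds a 3D grid of absolute dose in Gy on the voxel grid of
#' the patient case it belongs to, together with the delivery technique that
#' produced it.
#'
#' @param values 3D numeric array of dose in Gy (rows x cols x slices).
#' @param spacing numeric length-3 voxel spacing `(dx, dy, dz)` in mm.
#' @param technique `"3DCRT"` or `"IMRT"`.
#' @param case_id case identifier string.
#' @param prescription prescription dose in Gy (default 50 = 2 Gy x 25 fx).
#' @return An object of class `dose_map`.
#' @export
dose_map <- function(values, spacing, technique = c("3DCRT", "IMRT"),
                     case_id = "case", prescription = 50) {
  technique <- match.arg(technique)
  if (length(dim(values)) != 3L)
    stop("dose values must be a 3D array")
  if (any(values < 0))
    stop("dose values must be non-negative")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("voxel spacing must be three positive numbers")
  structure(
    list(values = values, spacing = as.numeric(spacing),
         technique = technique, case_id = case_id,
         prescription = prescription),
    class = "dose_map")
}

#' @export
print.dose_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dose_map> %s  %s  grid %dx%dx%d  spacing %.2fx%.2fx%.2f mm\n",
              x$case_id, x$technique, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  dose range [%.2f, %.2f] Gy, prescription %.1f Gy\n",
              min(x$values), max(x$values), x$prescription))
  invisible(x)
}

# internal: verify a dose map is aligned with a case grid
check_aligned <- function(dose, case) {
  if (!identical(dim(dose$values), dim(case$ct)))
    stop("dose grid is not aligned with the case grid")
  if (max(abs(dose$spacing - case$spacing)) > 1e-9)
    stop("dose voxel spacing differs from the case spacing")
  invisible(TRUE)
}

#' @export
print.patient_case <- function(x, ...) {
  d <- dim(x$ct)
  cat(sprintf("<patient_case> %s  [%s]  %s breast  grid %dx%dx%d  dz %.2f mm\n",
              x$case_id, x$institution, x$laterality, d[1], d[2], d[3],
              x$spacing[3]))
  cat(sprintf("  structures: %s\n", paste(names(x$masks), collapse = ", ")))
  cat(sprintf("  prescription %.1f Gy; node-positive: %s\n",
              x$prescription, !is.null(x$masks$ptv_nodes)))
  invisible(x)
}

#' Validate a patient case
#'
#' Checks the structural invariants of a [patient case][generate_case]:
#' every mask shares the CT grid and is strictly binary, organs lie inside
#' the body, the PTV/lung overlap is bounded, and the voxel spacing is
#' positive.
#'
#' @param case a `patient_case`.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_case <- function(case) {
  stopifnot(inherits(case, "patient_case"))
  d <- dim(case$ct)
  for (nm in names(case$masks)) {
    m <- case$masks[[nm]]
    if (!identical(dim(m), d))
      stop(sprintf("mask '%s' does not match the CT grid", nm))
    if (!all(m %in% c(0, 1)))
      stop(sprintf("mask '%s' is not {0,1}-valued", nm))
  }
  body <- case$masks$body
  for (nm in c("lung_ipsi", "lung_contra", "heart", "ptv_breast")) {
    if (any(case$masks[[nm]] > body))
      stop(sprintf("mask '%s' extends outside the body", nm))
  }
  n_ptv <- sum(case$masks$ptv_breast)
  ov <- sum(case$masks$ptv_breast * case$masks$lung_ipsi)
  if (n_ptv > 0 && ov >= 0.05 * n_ptv)
    stop("PTV/ipsilateral-lung overlap exceeds 5% of PTV volume")
  if (any(case$spacing <= 0)) stop("voxel spacing must be positive")
  invisible(TRUE)
}
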