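#' Cumulative dose-volume histogram
#'
#' Computes the cumulative DVH of a structure: the fraction of the
#' structure's volume receiving at least each dose level.
#'
#' @param dose a [dose_map] or a numeric array of dose in Gy.
#' @param mask binary array of the same shape selecting the structure.
#' @param bin_width histogram bin width in Gy (default 0.1). Curves are
#'   binned; the headline metrics in [extract_metrics()] bypass binning.
#' @param structure structure name carried into the result.
#' @param spacing voxel spacing in mm; taken from `dose` when it is a
#'   `dose_map`.
#' @return A `dvh_curve`: list with `dose_edges` (Gy), `volume_fraction`
#'   (non-increasing, starts at 1), `structure` and `total_volume` (cm^3),
#'   or a structure-absent marker when the mask is empty.
#' @export
compute_dvh <- function(dose, mask, bin_width = 0.1, structure = "structure",
                        spacing = NULL) {
  vals <- if (inherits(dose, "dose_map")) dose$values else dose
  if (is.null(spacing) && inherits(dose, "dose_map")) spacing <- dose$spacing
  if (!identical(dim(vals), dim(mask)))
    stop("dose and mask grids are not aligned")
  if (bin_width <= 0) stop("bin_width must be positive")
  n <- sum(mask != 0)
  vol_cc <- if (is.null(spacing)) NA_real_ else n * prod(spacing) / 1000
  if (n == 0L) {
    return(structure(list(dose_edges = numeric(0), volume_fraction = numeric(0),
                          structure = structure, total_volume = 0,
                          present = FALSE), class = "dvh_curve"))
  }
  d <- vals[mask != 0]
  edges <- seq(0, max(d) + bin_width, by = bin_width)
  frac <- vapply(edges, function(e) mean(d >= e), numeric(1))
  structure(list(dose_edges = edges, volume_fraction = frac,
                 structure = structure, total_volume = vol_cc,
                 present = TRUE), class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  if (!x$present) {
    cat(sprintf("<dvh_curve> %s: structure absent\n", x$structure))
  } else {
    cat(sprintf("<dvh_curve> %s: %d edges to %.1f Gy, volume %.1f cm^3\n",
                x$structure, length(x$dose_edges), max(x$dose_edges),
                x$total_volume))
  }
  invisible(x)
}

#' DVH metrics of a structure
#'
#' Computes the planning metrics used by the technique-selection rule:
#' mean dose, D95% (highest dose received by at least 95% of the volume,
#' linearly interpolated between voxel order statistics), V95% (volume
#' receiving at least 95% of the prescription), V20Gy and V25Gy. Volume
#' metrics are exact voxel counts in percent; no histogram binning is
#' involved.
#'
#' @inheritParams compute_dvh
#' @param prescription prescription dose in Gy.
#' @return A `dvh_metrics` object; for an empty mask, a structure-absent
#'   marker with all metrics `NA` (never zero).
#' @export
extract_metrics <- function(dose, mask, prescription = 50,
                            structure = "structure", spacing = NULL) {
  vals <- if (inherits(dose, "dose_map")) dose$values else dose
  if (is.null(spacing) && inherits(dose, "dose_map")) spacing <- dose$spacing
  if (!identical(dim(vals), dim(mask)))
    stop("dose and mask grids are not aligned")
  if (prescription <= 0) stop("prescription must be positive")
  n <- sum(mask != 0)
  if (n == 0L) {
    return(structure(list(structure = structure, present = FALSE,
                          Dmean = NA_real_, D95 = NA_real_, V95 = NA_real_,
                          V20Gy = NA_real_, V25Gy = NA_real_,
                          n_voxels = 0L, total_volume = 0),
                     class = "dvh_metrics"))
  }
  d <- vals[mask != 0]
  vol_cc <- if (is.null(spacing)) NA_real_ else n * prod(spacing) / 1000
  structure(list(
    structure = structure, present = TRUE,
    Dmean = mean(d),
    # dose received by >= 95% of the volume = lower 5% quantile of voxel
    # doses, linear interpolation between order statistics
    D95 = unname(stats::quantile(d, 0.05, type = 7)),
    V95 = 100 * mean(d >= 0.95 * prescription),
    V20Gy = 100 * mean(d >= 20),
    V25Gy = 100 * mean(d >= 25),
    n_voxels = as.integer(n), total_volume = vol_cc),
    class = "dvh_metrics")
}

#' @export
print.dvh_metrics <- function(x, ...) {
  if (!x$present) {
    cat(sprintf("<dvh_metrics> %s: structure absent\n", x$structure))
    return(invisible(x))
  }
  cat(sprintf(
    "<dvh_metrics> %s (%d voxels): Dmean %.2f Gy, D95 %.2f Gy, V95 %.1f%%, V20Gy %.1f%%, V25Gy %.1f%%\n",
    x$structure, x$n_voxels, x$Dmean, x$D95, x$V95, x$V20Gy, x$V25Gy))
  invisible(x)
}

#' Clinical-vs-predicted DVH metric differences
#'
#' Dose metrics (Dmean, D95) are compared as
#' `(clinical - predicted) / prescription x 100` (percent of prescription);
#' volume metrics (V95, V20Gy, V25Gy) as the direct difference
#' `clinical - predicted` in percentage points, without normalization.
#'
#' @param clinical,predicted `dvh_metrics` for the same structure.
#' @param prescription prescription dose in Gy.
#' @return data.frame with one row per metric: `metric`, `clinical`,
#'   `predicted`, `kind` (`dose_metric`/`volume_metric`) and
#'   `relative_delta`.
#' @export
compare_metrics <- function(clinical, predicted, prescription = 50) {
  stopifnot(inherits(clinical, "dvh_metrics"), inherits(predicted, "dvh_metrics"))
  if (prescription <= 0) stop("prescription must be positive")
  if (!identical(clinical$structure, predicted$structure))
    stop("metrics belong to different structures")
  rows <- rbind(
    data.frame(metric = c("Dmean", "D95"),
               clinical = c(clinical$Dmean, clinical$D95),
               predicted = c(predicted$Dmean, predicted$D95),
               kind = "dose_metric"),
    data.frame(metric = c("V95", "V20Gy", "V25Gy"),
               clinical = c(clinical$V95, clinical$V20Gy, clinical$V25Gy),
               predicted = c(predicted$V95, predicted$V20Gy, predicted$V25Gy),
               kind = "volume_metric"))
  rows$relative_delta <- ifelse(
    rows$kind == "dose_metric",
    (rows$clinical - rows$predicted) / prescription * 100,
    rows$clinical - rows$predicted)
  rows$structure <- clinical$structure
  rows
}

#' Cohort mean +/- SD table of metric differences
#'
#' Aggregates per-case metric differences into a mean and sample-SD table
#' per (regime, structure, metric) cell. Cases whose structure is absent
#' (e.g. node-negative patients for the nodal PTV) carry `NA` deltas and
#' are excluded from their cell rather than zero-filled; cells with fewer
#' than two contributing cases are dropped.
#'
#' @param deltas data.frame with columns `regime`, `structure`, `metric`,
#'   `relative_delta` (one row per case x metric).
#' @return data.frame with `regime`, `structure`, `metric`, `n`, `mean`,
#'   `sd`.
#' @export
cohort_metric_table <- function(deltas) {
  need <- c("regime", "structure", "metric", "relative_delta")
  if (!all(need %in% names(deltas)))
    stop("deltas must have columns regime, structure, metric, relative_delta")
  deltas <- deltas[!is.na(deltas$relative_delta), , drop = FALSE]
  if (nrow(deltas) == 0L)
    return(data.frame(regime = character(0), structure = character(0),
                      metric = character(0), n = integer(0),
                      mean = numeric(0), sd = numeric(0)))
  key <- interaction(deltas$regime, deltas$structure, deltas$metric, drop = TRUE)
  out <- do.call(rbind, lapply(split(deltas, key), function(g) {
    data.frame(regime = g$regime[1], structure = g$structure[1],
               metric = g$metric[1], n = nrow(g),
               mean = mean(g$relative_delta),
               sd = stats::sd(g$relative_delta))
  }))
  rownames(out) <- NULL
  out <- out[out$n >= 2L, , drop = FALSE]
  out[order(out$regime, out$structure, out$metric), , drop = FALSE]
}
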