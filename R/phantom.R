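#' Cohort specification for the synthetic phantom generator
#'
#' Describes one institutional cohort of synthetic breast-radiotherapy
#' phantoms: the grid, the axial sampling (slice thickness 3.75 mm for
#' `inst1`, 3 mm for `inst2`) and the anatomical-complexity distribution.
#' Complexity is governed by four per-case covariates drawn uniformly from
#' the configured ranges:
#'
#' * `heart_proximity` in `[0,1]` — 0 places the heart ~40 mm behind the
#'   chest wall, 1 puts it almost abutting it (drives heart dose under
#'   tangential fields); the default upper bound of 0.8 yields a referral
#'   population in which roughly three quarters of cases are conformally
#'   treatable;
#' * `ptv_size` — multiplicative scale of the breast PTV (drives how much
#'   ipsilateral lung the tangent corridor clips);
#' * `curvature` — multiplicative scale of the antero-posterior chest
#'   diameter (flatter chests expose more lung);
#' * `node_positive_prob` — probability that the case carries a nodal PTV.
#'
#' The `inst2` defaults emulate a mixed 3D-CRT/IMRT referral population
#' with a broader complexity mix; `inst1` a 3D-CRT-only population.
#'
#' @param n_cases number of cases (>= 1).
#' @param institution `"inst1"` or `"inst2"`.
#' @param seed integer seed; the full cohort is a pure function of the spec.
#' @param grid_n in-plane grid size in pixels (square).
#' @param pixel_mm in-plane pixel spacing in mm.
#' @param n_slices number of axial slices per phantom.
#' @param heart_proximity_range,ptv_size_range,curvature_range numeric
#'   length-2 ranges of the covariates.
#' @param node_positive_prob probability of a nodal PTV; defaults follow
#'   the institutional node-positive fractions (0.75 / 0.36).
#' @param left_prob probability of a left-sided case.
#' @return a `cohort_spec`.
#' @export
cohort_spec <- function(n_cases, institution = c("inst1", "inst2"), seed = 1,
                        grid_n = 80, pixel_mm = 4, n_slices = 10,
                        heart_proximity_range = c(0, 0.8),
                        ptv_size_range = c(0.75, 1.3),
                        curvature_range = c(0.8, 1.1),
                        node_positive_prob = NULL,
                        left_prob = 0.5) {
  institution <- match.arg(institution)
  if (is.null(node_positive_prob))
    node_positive_prob <- if (institution == "inst1") 0.75 else 0.36
  chk_range <- function(x, nm, lo, hi) {
    if (length(x) != 2 || any(!is.finite(x)) || x[1] > x[2] ||
        x[1] < lo || x[2] > hi)
      stop(sprintf("invalid cohort spec: '%s' must be an ordered range within [%g, %g]",
                   nm, lo, hi))
  }
  if (n_cases < 1) stop("invalid cohort spec: 'n_cases' must be >= 1")
  if (grid_n < 32) stop("invalid cohort spec: 'grid_n' must be >= 32")
  if (pixel_mm <= 0) stop("invalid cohort spec: 'pixel_mm' must be positive")
  if (n_slices < 4) stop("invalid cohort spec: 'n_slices' must be >= 4")
  chk_range(heart_proximity_range, "heart_proximity_range", 0, 1)
  chk_range(ptv_size_range, "ptv_size_range", 0.4, 1.8)
  chk_range(curvature_range, "curvature_range", 0.5, 1.5)
  if (node_positive_prob < 0 || node_positive_prob > 1)
    stop("invalid cohort spec: 'node_positive_prob' must be in [0, 1]")
  if (left_prob < 0 || left_prob > 1)
    stop("invalid cohort spec: 'left_prob' must be in [0, 1]")
  structure(list(
    n_cases = as.integer(n_cases), institution = institution,
    seed = as.integer(seed), grid_n = as.integer(grid_n),
    pixel_mm = pixel_mm, n_slices = as.integer(n_slices),
    slice_mm = if (institution == "inst1") 3.75 else 3.0,
    heart_proximity_range = heart_proximity_range,
    ptv_size_range = ptv_size_range,
    curvature_range = curvature_range,
    node_positive_prob = node_positive_prob,
    left_prob = left_prob), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %s: %d cases, %dx%dx%d grid, %.2gx%.2gx%.2f mm, seed %d\n",
              x$institution, x$n_cases, x$grid_n, x$grid_n, x$n_slices,
              x$pixel_mm, x$pixel_mm, x$slice_mm, x$seed))
  cat(sprintf("  heart proximity %s, PTV size %s, curvature %s, P(node+) %.2f, P(left) %.2f\n",
              paste(x$heart_proximity_range, collapse = "-"),
              paste(x$ptv_size_range, collapse = "-"),
              paste(x$curvature_range, collapse = "-"),
              x$node_positive_prob, x$left_prob))
  invisible(x)
}

# internal: elliptical binary mask on coordinate matrices X, Y (mm)
ellipse_mask <- function(X, Y, cx, cy, a, b) {
  ((X - cx) / a)^2 + ((Y - cy) / b)^2 <= 1
}

#' Generate one synthetic patient case
#'
#' Builds a pseudo-3D thorax phantom: an elliptical body with two lungs, a
#' heart whose chest-wall distance is set by the `heart_proximity`
#' covariate, a breast mound carrying the breast PTV on the configured
#' laterality, and (for node-positive cases) a nodal PTV on the superior
#' slices. Cross-sections vary slowly along the axial direction. CT-like
#' intensities are approximately 0 HU in soft tissue, -700 HU in lung and
#' -1000 HU in air, with mild Gaussian noise.
#'
#' @param spec a [cohort_spec()].
#' @param index case index (1-based, `<= spec$n_cases`).
#' @return a `patient_case`: `case_id`, `ct` (3D array, HU),
#'   `spacing` (dx, dy, dz in mm), `masks` (binary arrays: `body`,
#'   `lung_ipsi`, `lung_contra`, `heart`, `ptv_breast`, and `ptv_nodes`
#'   when node-positive), `laterality`, `prescription` (50 Gy),
#'   `institution`, and the drawn `covariates`.
#' @export
generate_case <- function(spec, index) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (index < 1 || index > spec$n_cases)
    stop("index must lie in [1, spec$n_cases]")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed((spec$seed * 10007L + as.integer(index) * 7919L) %% 2147483647L)

  runif_r <- function(r) stats::runif(1, r[1], r[2])
  cov <- list(
    heart_proximity = runif_r(spec$heart_proximity_range),
    ptv_size = runif_r(spec$ptv_size_range),
    curvature = runif_r(spec$curvature_range),
    body_scale = stats::runif(1, 0.92, 1.05),
    node_positive = stats::runif(1) < spec$node_positive_prob,
    laterality = if (stats::runif(1) < spec$left_prob) "left" else "right",
    ripple_phase = stats::runif(1, 0, 2 * pi))

  n <- spec$grid_n; dx <- spec$pixel_mm; nz <- spec$n_slices
  fov <- n * dx
  xs <- (seq_len(n) - 0.5) * dx
  X <- matrix(xs, n, n, byrow = TRUE)  # columns = x (patient left at +x)
  Y <- matrix(xs, n, n)                # rows = y (posterior at +y)
  xc <- fov / 2; yc <- 0.56 * fov
  s <- if (cov$laterality == "left") 1 else -1

  zero <- array(0, c(n, n, nz))
  masks <- list(body = zero, lung_ipsi = zero, lung_contra = zero,
                heart = zero, ptv_breast = zero)
  if (cov$node_positive) masks$ptv_nodes <- zero
  ct <- array(-1000, c(n, n, nz))

  for (iz in seq_len(nz)) {
    zf <- (iz - 0.5) / nz                       # 0 = superior, 1 = inferior
    f <- 1 - 0.10 * ((zf - 0.5) / 0.5)^2        # slow axial size variation
    a_b <- 0.40 * fov * cov$body_scale * f
    b_b <- 0.27 * fov * cov$body_scale * cov$curvature * f
    thorax <- ellipse_mask(X, Y, xc, yc, a_b, b_b)

    # breast mound centred on the anterior body surface, laterality side
    cth <- s * 0.55; sth <- sqrt(1 - cth^2)
    x_br <- xc + a_b * cth; y_br <- yc - b_b * sth
    qz <- cov$ptv_size * (1 - 0.8 * ((zf - 0.5) / 0.35)^2)
    has_breast <- qz > 0.25 * cov$ptv_size
    breast <- if (has_breast)
      ellipse_mask(X, Y, x_br, y_br, 38 * qz, 27 * qz) else
      matrix(FALSE, n, n)
    body <- thorax | breast

    # lungs
    lungL <- ellipse_mask(X, Y, xc + 0.45 * a_b, yc + 0.05 * b_b,
                          0.34 * a_b, 0.62 * b_b)
    lungR <- ellipse_mask(X, Y, xc - 0.45 * a_b, yc + 0.05 * b_b,
                          0.34 * a_b, 0.62 * b_b)

    # heart: anterior-left, chest-wall gap set by the proximity covariate
    heart <- matrix(FALSE, n, n)
    if (zf >= 0.35) {
      a_h <- 0.16 * a_b; b_h <- 0.20 * b_b
      x_h <- xc + 0.16 * a_b
      y_front <- yc - b_b * sqrt(pmax(0, 1 - ((x_h - xc) / a_b)^2))
      gap <- 4 + (1 - cov$heart_proximity) * 40   # mm
      y_h <- y_front + gap + b_h
      heart <- ellipse_mask(X, Y, x_h, y_h, a_h, b_h) & thorax
    }
    lungL <- lungL & !heart; lungR <- lungR & !heart
    lung_ipsi <- if (s > 0) lungL else lungR
    lung_contra <- if (s > 0) lungR else lungL

    ptv <- breast & body & !lungL & !lungR

    nodes <- matrix(FALSE, n, n)
    if (cov$node_positive && zf <= 0.28) {
      x_n <- xc + s * 0.22 * a_b
      y_fn <- yc - b_b * sqrt(pmax(0, 1 - ((x_n - xc) / a_b)^2))
      nodes <- ellipse_mask(X, Y, x_n, y_fn + 14, 13 * f, 10 * f) &
        thorax & !lungL & !lungR & !heart
    }

    masks$body[, , iz] <- body * 1
    masks$lung_ipsi[, , iz] <- lung_ipsi * 1
    masks$lung_contra[, , iz] <- lung_contra * 1
    masks$heart[, , iz] <- heart * 1
    masks$ptv_breast[, , iz] <- ptv * 1
    if (cov$node_positive) masks$ptv_nodes[, , iz] <- nodes * 1

    sl <- matrix(-1000, n, n)
    sl[body] <- stats::rnorm(sum(body), 0, 15)
    sl[breast & body] <- stats::rnorm(sum(breast & body), -60, 15)
    lungs <- lungL | lungR
    sl[lungs] <- stats::rnorm(sum(lungs), -700, 30)
    sl[heart] <- stats::rnorm(sum(heart), 20, 15)
    ct[, , iz] <- sl
  }

  structure(list(
    case_id = sprintf("%s_case%03d", spec$institution, index),
    ct = ct, spacing = c(dx, dx, spec$slice_mm), masks = masks,
    laterality = cov$laterality, prescription = 50,
    institution = spec$institution, covariates = cov),
    class = "patient_case")
}

# save/restore the global RNG state so generators are pure functions
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# internal: case-level tangential beam basis (unit vectors u along the
# beam axis, v along the perpendicular, v pointing posterior)
beam_basis <- function(case) {
  fov <- dim(case$ct)[1] * case$spacing[1]
  a_b <- 0.40 * fov * case$covariates$body_scale
  b_b <- 0.27 * fov * case$covariates$body_scale * case$covariates$curvature
  s <- if (case$laterality == "left") 1 else -1
  cth <- s * 0.55; sth <- sqrt(1 - cth^2)
  d <- c(-a_b * sth, -b_b * cth)          # chest-wall tangent at the breast
  u <- d / sqrt(sum(d^2))
  v <- c(u[2], -u[1])
  if (v[2] < 0) v <- -v                   # v points posterior
  list(u = u, v = v)
}

#' Tangential-field dose-engine parameters
#'
#' Constants of the analytic dose engines. The engines are geometric
#' surrogates, not transport calculations: the 3D-CRT engine fills an
#' opposed-tangent beam corridor fitted to the PTV with prescription dose,
#' a sigmoidal lateral penumbra and a small exponential scatter bath; the
#' IMRT engine delivers a conformal high-dose region hugging the PTV, a
#' broader entrance/exit bath along the same tangential corridor, and an
#' optimizer-like dose suppression over the heart away from the PTV.
#' All lengths in mm, amplitudes as fractions of the prescription.
#'
#' @param technique `"3DCRT"` or `"IMRT"`.
#' @return named list of engine constants.
#' @export
dose_engine_params <- function(technique = c("3DCRT", "IMRT")) {
  technique <- match.arg(technique)
  if (technique == "3DCRT") {
    list(margin = 8, penumbra = 2.5, ripple_amp = 0.04, ripple_period = 90,
         bath_amp = 0.04, bath_decay = 25, axial_decay = 15, dose_cap = 1.25)
  } else {
    list(margin = 7, penumbra = 2, ripple_amp = 0.015, ripple_period = 90,
         corridor_amp = 0.14, corridor_decay = 60,
         scatter_amp = 0.05, scatter_decay = 50,
         avoid_depth = 0.85, avoid_margin = 8, avoid_sigma = 4,
         avoid_gate = 10, avoid_gate_sigma = 4,
         axial_decay = 15, dose_cap = 1.25)
  }
}

# internal: per-slice PTV bookkeeping shared by both engines. Returns for
# each slice the index of the slice whose PTV defines its dose pattern
# (itself if it has PTV, else the nearest PTV-bearing slice) and the
# axial attenuation factor.
ptv_slice_plan <- function(case, axial_decay) {
  nz <- dim(case$ct)[3]
  ptv <- case$masks$ptv_breast
  if (!is.null(case$masks$ptv_nodes)) ptv <- pmax(ptv, case$masks$ptv_nodes)
  has <- vapply(seq_len(nz), function(iz) any(ptv[, , iz] != 0), logical(1))
  if (!any(has)) return(NULL)
  src <- integer(nz); attn <- numeric(nz)
  withz <- which(has)
  for (iz in seq_len(nz)) {
    j <- withz[which.min(abs(withz - iz))]
    src[iz] <- j
    attn[iz] <- exp(-abs(iz - j) * case$spacing[3] / axial_decay)
  }
  list(ptv = ptv, src = src, attn = attn)
}

# internal: coordinate matrices (mm) for a case grid
grid_coords <- function(case) {
  n <- dim(case$ct)[1]; dx <- case$spacing[1]
  xs <- (seq_len(n) - 0.5) * dx
  list(X = matrix(xs, n, n, byrow = TRUE), Y = matrix(xs, n, n))
}

#' Simulate a tangential 3D-CRT dose distribution
#'
#' Analytic surrogate of an opposed tangential-field plan: the corridor
#' between the two tangents fitted to the PTV (plus margin) receives the
#' prescription dose with a wedge-like along-beam ripple and a sigmoidal
#' penumbra; outside the corridor a small exponential scatter bath
#' remains. Organ-at-risk dose therefore grows monotonically with the
#' geometric overlap between the corridor and the organ. Deterministic
#' given the case and parameters. A case without any PTV receives zero
#' dose.
#'
#' @param case a [patient_case][generate_case].
#' @param params engine constants, see [dose_engine_params()].
#' @return a [dose_map] with `technique = "3DCRT"`.
#' @export
simulate_dose_3dcrt <- function(case, params = dose_engine_params("3DCRT")) {
  validate_case(case)
  rx <- case$prescription
  n <- dim(case$ct)[1]; nz <- dim(case$ct)[3]
  out <- array(0, dim(case$ct))
  plan <- ptv_slice_plan(case, params$axial_decay)
  if (is.null(plan))
    return(dose_map(out, case$spacing, "3DCRT", case$case_id, rx))
  bb <- beam_basis(case); g <- grid_coords(case)
  U <- g$X * bb$u[1] + g$Y * bb$u[2]
  V <- g$X * bb$v[1] + g$Y * bb$v[2]
  phi <- case$covariates$ripple_phase
  for (iz in seq_len(nz)) {
    pm <- plan$ptv[, , plan$src[iz]]
    pv <- V[pm != 0]
    ssd <- pmax(V - (max(pv) + params$margin), (min(pv) - params$margin) - V)
    profile <- stats::plogis(-ssd / params$penumbra)
    ripple <- 1 + params$ripple_amp * sin(2 * pi * U / params$ripple_period + phi)
    comp <- rx * profile * ripple
    bath <- rx * params$bath_amp * exp(-pmax(ssd, 0) / params$bath_decay)
    d <- pmax(comp, bath) * plan$attn[iz] * (case$masks$body[, , iz] != 0)
    out[, , iz] <- pmin(pmax(d, 0), params$dose_cap * rx)
  }
  dose_map(out, case$spacing, "3DCRT", case$case_id, rx)
}

# internal: Euclidean distance (mm) outside a binary mask; Inf-like large
# value when the mask is empty on the slice
dist_outside <- function(mask, dx) {
  if (!any(mask != 0)) return(matrix(1e6, nrow(mask), ncol(mask)))
  m <- EBImage::distmap(1 - mask)
  as.matrix(m) * dx
}

#' Simulate an inverse-planned IMRT dose distribution
#'
#' Analytic surrogate of a tangential-incidence IMRT plan: a conformal
#' high-dose region hugging the PTV (tighter and more homogeneous than
#' the 3D-CRT corridor), a broader low-dose entrance/exit bath along the
#' same tangential corridor — reproducing the larger low-dose bath of
#' modulated plans — and an optimizer-like suppression of dose over the
#' heart wherever that does not compromise PTV coverage. Relative to
#' [simulate_dose_3dcrt()] on the same case, PTV homogeneity is equal or
#' better, high-dose spill into heart and lung is equal or lower, and the
#' body volume in the 1-10 Gy bath is equal or higher.
#'
#' @inheritParams simulate_dose_3dcrt
#' @return a [dose_map] with `technique = "IMRT"`.
#' @export
simulate_dose_imrt <- function(case, params = dose_engine_params("IMRT")) {
  validate_case(case)
  rx <- case$prescription
  n <- dim(case$ct)[1]; nz <- dim(case$ct)[3]
  dx <- case$spacing[1]
  out <- array(0, dim(case$ct))
  plan <- ptv_slice_plan(case, params$axial_decay)
  if (is.null(plan))
    return(dose_map(out, case$spacing, "IMRT", case$case_id, rx))
  bb <- beam_basis(case); g <- grid_coords(case)
  U <- g$X * bb$u[1] + g$Y * bb$u[2]
  V <- g$X * bb$v[1] + g$Y * bb$v[2]
  phi <- case$covariates$ripple_phase
  for (iz in seq_len(nz)) {
    pm <- plan$ptv[, , plan$src[iz]]
    pv <- V[pm != 0]
    ssd <- pmax(V - (max(pv) + params$margin), (min(pv) - params$margin) - V)
    dp <- dist_outside(pm, dx)
    dh <- dist_outside(case$masks$heart[, , iz], dx)
    ripple <- 1 + params$ripple_amp * sin(2 * pi * U / params$ripple_period + phi)
    conformal <- rx * stats::plogis(-(dp - params$margin) / params$penumbra) * ripple
    corridor <- rx * params$corridor_amp * exp(-pmax(ssd, 0) / params$corridor_decay)
    scatter <- rx * params$scatter_amp * exp(-dp / params$scatter_decay)
    avoid <- 1 - params$avoid_depth *
      stats::plogis((params$avoid_margin - dh) / params$avoid_sigma) *
      stats::plogis((dp - params$avoid_gate) / params$avoid_gate_sigma)
    d <- avoid * pmax(conformal, corridor, scatter) *
      plan$attn[iz] * (case$masks$body[, , iz] != 0)
    out[, , iz] <- pmin(pmax(d, 0), params$dose_cap * rx)
  }
  dose_map(out, case$spacing, "IMRT", case$case_id, rx)
}

#' Generate a full synthetic cohort with paired doses and labels
#'
#' Generates every case of a [cohort_spec()], simulates both the 3D-CRT
#' and the IMRT dose on each, and assigns the ground-truth technique label
#' by applying the organ-at-risk constraint set to the *simulated* (not
#' predicted) 3D-CRT dose: the label is `3DCRT` when that dose passes all
#' constraints, `IMRT` otherwise — the same rule an observer applying the
#' clinical criteria to the reference plans would use.
#'
#' @param spec a [cohort_spec()].
#' @param constraints a [constraint_set()].
#' @return a `phantom_cohort`: list of entries, each with `case`,
#'   `dose_crt`, `dose_imrt`, `label`, `crt_pass`, `imrt_pass`.
#' @export
generate_cohort <- function(spec, constraints = constraint_set()) {
  stopifnot(inherits(spec, "cohort_spec"))
  entries <- lapply(seq_len(spec$n_cases), function(i) {
    case <- generate_case(spec, i)
    d_crt <- simulate_dose_3dcrt(case)
    d_imrt <- simulate_dose_imrt(case)
    m <- function(dm) list(
      lung = extract_metrics(dm, case$masks$lung_ipsi, case$prescription,
                             "lung_ipsi", case$spacing),
      heart = extract_metrics(dm, case$masks$heart, case$prescription,
                              "heart", case$spacing))
    crt <- check_constraints(m(d_crt), constraints)
    imrt <- check_constraints(m(d_imrt), constraints)
    list(case = case, dose_crt = d_crt, dose_imrt = d_imrt,
         label = if (crt$pass) "3DCRT" else "IMRT",
         crt_pass = crt$pass, imrt_pass = imrt$pass)
  })
  structure(entries, class = "phantom_cohort", spec = spec)
}

#' @export
print.phantom_cohort <- function(x, ...) {
  spec <- attr(x, "spec")
  labels <- vapply(x, `[[`, character(1), "label")
  cat(sprintf("<phantom_cohort> %s: %d cases (%d 3DCRT / %d IMRT labels)\n",
              spec$institution, length(x),
              sum(labels == "3DCRT"), sum(labels == "IMRT")))
  invisible(x)
}

#' Persist a cohort to disk
#'
#' Writes one array-container file per case (`<case_id>.rds` holding the
#' case, both dose maps and the label) plus a tab-delimited
#' `manifest.tsv` with per-case metadata.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return the manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- do.call(rbind, lapply(cohort, function(e) {
    saveRDS(e, file.path(dir, paste0(e$case$case_id, ".rds")))
    data.frame(case_id = e$case$case_id,
               institution = e$case$institution,
               laterality = e$case$laterality,
               node_positive = !is.null(e$case$masks$ptv_nodes),
               label = e$label, crt_pass = e$crt_pass,
               imrt_pass = e$imrt_pass,
               heart_proximity = e$case$covariates$heart_proximity,
               ptv_size = e$case$covariates$ptv_size,
               curvature = e$case$covariates$curvature)
  }))
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
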