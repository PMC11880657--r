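# shared fixtures: tiny phantoms and independent brute-force oracles

small_spec <- function(n = 2, institution = "inst1", seed = 101, ...) {
  cohort_spec(n, institution, seed = seed, grid_n = 64, pixel_mm = 5,
              n_slices = 8, ...)
}

# a single case with fixed covariates via degenerate ranges
fixed_case <- function(heart_proximity = 0.2, ptv_size = 1, curvature = 1,
                       seed = 77, institution = "inst2", left = TRUE) {
  spec <- cohort_spec(1, institution, seed = seed, grid_n = 64, pixel_mm = 5,
                      n_slices = 8,
                      heart_proximity_range = rep(heart_proximity, 2),
                      ptv_size_range = rep(ptv_size, 2),
                      curvature_range = rep(curvature, 2),
                      left_prob = if (left) 1 else 0)
  generate_case(spec, 1)
}

# brute-force DVH metric oracle by explicit voxel enumeration
brute_metrics <- function(dose_values, mask, prescription) {
  d <- c()
  for (i in seq_along(mask)) if (mask[i] != 0) d <- c(d, dose_values[i])
  n <- length(d)
  ds <- sort(d)
  # D95: largest dose t with >= 95% of voxels receiving >= t, linearly
  # interpolated between order statistics (quantile definition, type 7)
  h <- (n - 1) * 0.05
  lo <- floor(h) + 1
  d95 <- if (lo >= n) ds[n] else ds[lo] + (h - (lo - 1)) * (ds[lo + 1] - ds[lo])
  list(Dmean = sum(d) / n,
       D95 = d95,
       V95 = 100 * sum(d >= 0.95 * prescription) / n,
       V20Gy = 100 * sum(d >= 20) / n,
       V25Gy = 100 * sum(d >= 25) / n)
}

# brute-force Dice by explicit set enumeration
brute_dsc <- function(a, b) {
  ia <- which(a != 0); ib <- which(b != 0)
  if (length(ia) + length(ib) == 0) return(1)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}

# brute-force nearest-source resampling: for each output pixel centre,
# scan all source pixels for the nearest centre (pixel-centre alignment;
# exact ties between two source centres go to the larger index, as
# documented)
brute_resample_nn <- function(grid, out_size) {
  nearest <- function(n_src, pos) {
    d <- abs(seq_len(n_src) - 0.5 - pos)
    max(which(d == min(d)))
  }
  nr <- nrow(grid); nc <- ncol(grid)
  out <- matrix(0, out_size[1], out_size[2])
  for (i in seq_len(out_size[1])) {
    for (j in seq_len(out_size[2])) {
      ri <- nearest(nr, (i - 0.5) * nr / out_size[1])
      cj <- nearest(nc, (j - 0.5) * nc / out_size[2])
      out[i, j] <- grid[ri, cj]
    }
  }
  out
}

# brute-force classification metrics from raw label pairs
brute_report <- function(truth, decided) {
  tp <- sum(decided == "3DCRT" & truth == "3DCRT")
  fp <- sum(decided == "3DCRT" & truth == "IMRT")
  fn <- sum(decided == "IMRT" & truth == "3DCRT")
  tn <- sum(decided == "IMRT" & truth == "IMRT")
  list(accuracy = 100 * (tp + tn) / length(truth),
       recall = if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn),
       precision = if (tp + fp == 0) NA_real_ else 100 * tp / (tp + fp))
}

# wrap a 3D dose array in a dose_map with unit spacing
as_dm <- function(values, technique = "3DCRT", prescription = 50) {
  dose_map(values, c(1, 1, 1), technique, "t", prescription)
}
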