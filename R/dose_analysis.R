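# Validation metrics: depth-dose curves, 3D gamma analysis, plan indices.

#' Integrated depth dose
#'
#' Sum of dose times voxel volume over each transverse plane, as a function
#' of depth along the beam axis (the grid's z axis). Depths are returned from
#' the beam entrance (highest z) downward.
#'
#' @param dose A `vpmc_grid`/`vpmc_dose`.
#' @return Data frame with `z` (voxel-center position, mm), `depth` (mm below
#'   the first slice) and `idd`.
#' @export
idd <- function(dose) {
  vol <- prod(dose$spacing)
  z <- grid_axis(dose, 3)
  v <- apply(dose$values, 3, sum) * vol
  ord <- order(z, decreasing = TRUE)
  data.frame(z = z[ord], depth = z[ord][1] - z[ord], idd = v[ord])
}

#' Percentage depth dose
#'
#' Central-axis depth profile normalized so its maximum is 100%.
#'
#' @param dose A `vpmc_grid`/`vpmc_dose`.
#' @param axis_xy Lateral position (mm) of the profile line; the nearest
#'   voxel column is used.
#' @return Data frame with `z`, `depth` and `pdd` (% of the profile maximum).
#' @export
pdd <- function(dose, axis_xy = c(0, 0)) {
  ix <- which.min(abs(grid_axis(dose, 1) - axis_xy[1]))
  iy <- which.min(abs(grid_axis(dose, 2) - axis_xy[2]))
  prof <- dose$values[ix, iy, ]
  if (all(prof == 0)) stop("all-zero central-axis profile: PDD undefined")
  z <- grid_axis(dose, 3)
  ord <- order(z, decreasing = TRUE)
  data.frame(z = z[ord], depth = z[ord][1] - z[ord],
             pdd = 100 * prof[ord] / max(prof))
}

#' Gamma-analysis criteria
#'
#' @param dose_pct Dose-difference criterion, % of the global reference
#'   maximum.
#' @param dta_mm Distance-to-agreement criterion, mm.
#' @param threshold_pct Low-dose threshold, % of the reference maximum;
#'   reference voxels below it are not evaluated.
#' @return A `vpmc_gamma_criteria`.
#' @export
gamma_criteria <- function(dose_pct = 2, dta_mm = 2, threshold_pct = 10) {
  if (dose_pct <= 0 || dta_mm <= 0 || threshold_pct <= 0) {
    stop("all gamma criteria must be strictly positive")
  }
  structure(list(dose_pct = dose_pct, dta_mm = dta_mm,
                 threshold_pct = threshold_pct),
            class = "vpmc_gamma_criteria")
}

#' Resample a grid onto the frame of another
#'
#' Trilinear interpolation of `grid` at the voxel centers of `frame`;
#' positions outside `grid` get zero.
#'
#' @param grid Grid to resample.
#' @param frame Grid defining the target frame.
#' @return A `vpmc_grid` on `frame`'s frame.
#' @export
resample_grid <- function(grid, frame) {
  ax <- lapply(1:3, function(a) {
    (grid_axis(frame, a) - grid$origin[a]) / grid$spacing[a]
  })
  co <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  n <- grid$dims
  i0 <- pmin(pmax(floor(co$x), 0), n[1] - 2); fx <- co$x - i0
  j0 <- pmin(pmax(floor(co$y), 0), n[2] - 2); fy <- co$y - j0
  k0 <- pmin(pmax(floor(co$z), 0), n[3] - 2); fz <- co$z - k0
  inside <- co$x >= 0 & co$x <= n[1] - 1 & co$y >= 0 & co$y <= n[2] - 1 &
    co$z >= 0 & co$z <= n[3] - 1
  g <- grid$values
  idx <- function(i, j, k) 1 + i + n[1] * (j + n[2] * k)
  val <- (1 - fz) * ((1 - fy) * ((1 - fx) * g[idx(i0, j0, k0)] + fx * g[idx(i0 + 1, j0, k0)]) +
                     fy * ((1 - fx) * g[idx(i0, j0 + 1, k0)] + fx * g[idx(i0 + 1, j0 + 1, k0)])) +
    fz * ((1 - fy) * ((1 - fx) * g[idx(i0, j0, k0 + 1)] + fx * g[idx(i0 + 1, j0, k0 + 1)]) +
          fy * ((1 - fx) * g[idx(i0, j0 + 1, k0 + 1)] + fx * g[idx(i0 + 1, j0 + 1, k0 + 1)]))
  val[!inside] <- 0
  vpmc_grid(array(val, dim = frame$dims), frame$origin, frame$spacing)
}

#' 3D gamma analysis
#'
#' Global gamma: the dose-difference criterion is a percentage of the
#' reference grid's maximum (the normalization is deliberately asymmetric in
#' reference vs evaluated). For every reference voxel above the low-dose
#' threshold, the gamma index is minimized over positions within
#' `search_factor` times the DTA, sampling the evaluated grid by trilinear
#' interpolation on a DTA/`subdiv` lattice. The pass rate is the percentage
#' of evaluated reference voxels with gamma <= 1. If the two grids' frames
#' differ, the evaluated grid is resampled onto the reference frame first.
#'
#' @param reference,evaluated `vpmc_grid`/`vpmc_dose` objects.
#' @param criteria A [gamma_criteria()].
#' @param search_factor Search radius in units of the DTA.
#' @param subdiv Subsampling fineness (samples per DTA).
#' @return List with `gamma` (array, `NA` below threshold), `pass_rate` (%),
#'   `n_evaluated` and the criteria used.
#' @export
gamma3d <- function(reference, evaluated, criteria = gamma_criteria(),
                    search_factor = 3, subdiv = 10) {
  if (!isTRUE(all.equal(reference$dims, evaluated$dims)) ||
      !isTRUE(all.equal(reference$spacing, evaluated$spacing)) ||
      !isTRUE(all.equal(reference$origin, evaluated$origin))) {
    evaluated <- resample_grid(evaluated, reference)
  }
  out <- cpp_gamma(as.double(reference$values), as.double(evaluated$values),
                   as.integer(reference$dims), reference$spacing,
                   criteria$dose_pct, criteria$dta_mm, criteria$threshold_pct,
                   search_factor, as.integer(subdiv))
  list(gamma = array(out$gamma, dim = reference$dims),
       pass_rate = out$pass_rate, n_evaluated = out$n_evaluated,
       criteria = criteria)
}

#' Target dose-volume plan indices
#'
#' Computes the four plan-quality indices used for target dose-volume
#' constraints: `V100` — percentage of structure-of-interest (SOI) voxels
#' receiving at least the prescription; `Dmin` — minimum SOI dose as a
#' percentage of the prescription; `CI100` — conformity index, the ratio of
#' the volume enclosed by the 100% iso-dose (anywhere in the grid) to the
#' SOI volume; `RHI100` — radical dose homogeneity index, the maximum SOI
#' dose divided by the prescription.
#'
#' @param dose A `vpmc_grid`/`vpmc_dose`, or a bare numeric vector (then
#'   `mask` must be a logical/index vector on the same elements).
#' @param mask Logical array/vector selecting the SOI voxels; must be
#'   nonempty.
#' @param prescription Prescription dose (> 0), same units as `dose`.
#' @return Named list `V100`, `Dmin`, `CI100`, `RHI100`.
#' @export
plan_indices <- function(dose, mask, prescription) {
  v <- if (inherits(dose, "vpmc_grid")) as.numeric(dose$values) else as.numeric(dose)
  m <- as.logical(mask)
  if (!any(m)) stop("empty structure-of-interest mask")
  if (prescription <= 0) stop("prescription must be > 0")
  soi <- v[m]
  list(V100 = 100 * mean(soi >= prescription),
       Dmin = 100 * min(soi) / prescription,
       CI100 = sum(v >= prescription) / sum(m),
       RHI100 = max(soi) / prescription)
}
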