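# R-facing simulation interface shared by the two Monte Carlo engines.

.geom_for_kernel <- function(geometry) {
  ph <- geometry$phantom
  list(
    block = if (!is.null(geometry$aperture)) {
      list(z0 = geometry$aperture$distal_z, z1 = geometry$aperture$proximal_z,
           polygon = geometry$aperture$polygon)
    },
    shifter = geometry$shifter,
    phantom = list(origin = ph$origin, spacing = ph$spacing,
                   dims = as.integer(ph$dims),
                   values = as.double(ph$values)),
    source_z = geometry$source_z)
}

.default_tables <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- list(water = generate_tables(water_material()),
                     brass = generate_tables(brass_material()))
    }
    cache
  }
})

#' Default physics tables (water + brass, analytic mode)
#'
#' @return Named list of `vpmc_tables` with elements `water` and `brass`.
#' @export
default_tables <- function() .default_tables()

.allocate_histories <- function(spots, n_histories, batches) {
  w <- spots$weight
  if (all(w == 0)) stop("all spot weights are zero")
  m <- pmax(1L, as.integer(round(n_histories * w / sum(w) / batches)))
  m[w == 0] <- 0L
  m
}

.run_engine <- function(engine, spots, geometry, tables, n_histories, seed,
                        batches, nuclear, cutoff = 1, step = 1,
                        sec_frac = 0.5, sec_sigma = 0.2, max_steps = 20000L) {
  if (!inherits(geometry, "vpmc_beamline")) stop("geometry must be a vpmc_beamline")
  if (is.null(spots) || nrow(spots) == 0) stop("empty spot list")
  if (batches < 2) stop("need at least 2 batches for uncertainty estimation")
  if (n_histories < batches) stop("n_histories must be >= batches")
  m <- .allocate_histories(spots, n_histories, batches)
  keep <- m > 0
  out <- cpp_transport(engine, spots$energy[keep], spots$x[keep],
                       spots$y[keep], spots$sigma[keep], spots$weight[keep],
                       m[keep], .geom_for_kernel(geometry),
                       tables$water, tables$brass, as.integer(batches),
                       as.double(seed), nuclear, cutoff, step, sec_frac,
                       sec_sigma, as.integer(max_steps))
  ph <- geometry$phantom
  dims <- ph$dims
  dose <- array(out$dose, dim = dims)
  relse <- array(out$relse, dim = dims)
  hd <- dose > 0.5 * max(dose)
  meta <- list(engine = c("reference", "vp")[engine + 1], seed = seed,
               n_histories = sum(m) * batches, batches = batches,
               n_primaries = out$n_primaries, n_secondaries = out$n_secondaries,
               injected = out$injected, deposited = out$deposited,
               deposited_outside = out$deposited_outside,
               uncertainty = mean(relse[hd], na.rm = TRUE),
               nuclear = nuclear)
  structure(list(values = dose, origin = ph$origin, spacing = ph$spacing,
                 dims = dims, relse = relse, meta = meta),
            class = c("vpmc_dose", "vpmc_grid"))
}

#' Conventional condensed-history Monte Carlo simulation
#'
#' The reference engine: primaries are transported one at a time; at each
#' step energy loss, straggling and deflection are sampled from the material
#' tables, and a nuclear event may remove the primary and spawn a secondary
#' proton on the fly, which is then transported recursively. Dose is
#' accumulated per batch; the returned grid is the batch mean (per unit total
#' spot weight) with a per-voxel relative standard error across batches.
#' The run is deterministic for a fixed seed and batch layout: RNG streams
#' are counter-based per history.
#'
#' @param spots A [spot_list()].
#' @param geometry A [beamline_geometry()].
#' @param tables Named list with `water` and `brass` `vpmc_tables`
#'   (default: analytic tables).
#' @param n_histories Total number of primaries (>= `batches`).
#' @param seed Integer seed.
#' @param batches Number of statistically independent batches (>= 2).
#' @param nuclear Enable the nuclear removal / secondary model.
#' @return A `vpmc_dose`: a `vpmc_grid` with per-voxel `relse` and run
#'   metadata in `$meta` (the `uncertainty` entry is the mean relative
#'   standard error over voxels above 50% of the maximum dose).
#' @export
mc_simulate <- function(spots, geometry, tables = default_tables(),
                        n_histories = 1e5, seed = 1, batches = 10,
                        nuclear = TRUE) {
  .run_engine(0L, spots, geometry, tables, n_histories, seed, batches, nuclear)
}

#' Virtual-particle Monte Carlo simulation
#'
#' The VP engine: every particle of the run — one per primary and one per
#' pre-assigned secondary — is initialized before transport begins. Nuclear
#' conversion points are pre-sampled at initialization on a straight-line
#' ray trace through the geometry, so the per-step update rule is identical
#' for every VP (the same table lookups and random draws, with no branching
#' on particle fate or material — air and the aperture opening use
#' zero-valued tables). Dose conventions match [mc_simulate()] exactly, so
#' the two engines' grids are directly gamma-comparable.
#'
#' @inheritParams mc_simulate
#' @return A `vpmc_dose`.
#' @export
vp_simulate <- function(spots, geometry, tables = default_tables(),
                        n_histories = 1e5, seed = 1, batches = 10,
                        nuclear = TRUE) {
  .run_engine(1L, spots, geometry, tables, n_histories, seed, batches, nuclear)
}

#' @export
print.vpmc_dose <- function(x, ...) {
  cat(sprintf(
    "<vpmc_dose> %s engine, %s voxels, %g histories (%d batches)\n  max dose %.3g, mean rel. SE in >50%%-max voxels: %.2f%%\n",
    x$meta$engine, paste(x$dims, collapse = "x"), x$meta$n_histories,
    x$meta$batches, max(x$values), 100 * x$meta$uncertainty))
  invisible(x)
}
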