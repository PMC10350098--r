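# Virtual-particle ensemble: initialization before transport, and the
# uniform per-step update rule.

#' Initialize the virtual-particle ensemble
#'
#' Creates every VP of a run before any transport step: one VP per sampled
#' primary, plus one pre-assigned secondary VP for each primary whose nuclear
#' conversion is pre-sampled to occur. The conversion point is drawn by
#' combining an Exp(1) variate with the cumulative nuclear interaction depth
#' along the primary's straight-line path through the geometry (mean energy
#' loss only); the secondary VP is emitted up front at that point, carrying
#' half the local energy and a wide-Gaussian emission angle, and the primary
#' VP carries the matching deterministic deactivation depth. No VP is ever
#' created during transport.
#'
#' @param spots A [spot_list()].
#' @param geometry A [beamline_geometry()].
#' @param tables Named list with `water` and `brass` tables.
#' @param n_per_spot Primaries sampled per spot (>= 1).
#' @param seed Integer seed.
#' @param nuclear Enable the nuclear conversion model; with it disabled the
#'   ensemble contains exactly `n_per_spot * nrow(spots)` primary VPs.
#' @return Data frame (class `vpmc_ensemble`): one row per VP with `type`
#'   (0 primary, 1 secondary), `spot`, position, direction, `energy`,
#'   `weight`, `activation_depth` (mm along the beam axis from the source
#'   plane; 0 for primaries) and `deact_z` (conversion z for primaries).
#' @export
initialize_vps <- function(spots, geometry, tables = default_tables(),
                           n_per_spot = 1000, seed = 1, nuclear = TRUE) {
  if (n_per_spot < 1) stop("n_per_spot must be >= 1")
  ens <- cpp_init_vps(spots$energy, spots$x, spots$y, spots$sigma,
                      spots$weight, rep(as.integer(n_per_spot), nrow(spots)),
                      .geom_for_kernel(geometry), tables$water, tables$brass,
                      as.double(seed), nuclear, 1, 1, 0.5, 0.2)
  class(ens) <- c("vpmc_ensemble", class(ens))
  ens
}

#' One uniform VP transport step
#'
#' Advances every live VP of an ensemble by one step of at most `step` mm.
#' The code path is identical for every VP regardless of material or
#' generation: the material at the current position is classified (the
#' crossing-number test decides opening vs brass inside the block slab), the
#' corresponding tables are queried — air and the aperture opening use
#' zero-valued tables, so a VP there advances with unchanged energy and
#' direction — and energy loss, straggling and deflection are sampled with
#' exactly the same number of table lookups and random draws for every VP.
#' Dead VPs are no-ops. Uses R's RNG.
#'
#' @param ensemble A `vpmc_ensemble` (needs columns as from
#'   [initialize_vps()]; a logical column `alive` is added if absent).
#' @param geometry A [beamline_geometry()].
#' @param tables Named list with `water` and `brass` tables.
#' @param step Maximum step length (mm).
#' @return The updated ensemble. Attribute `deposits` holds a data frame of
#'   this step's energy deposits; attribute `ops` a matrix (one row per VP)
#'   counting table lookups and normal draws executed, which is constant
#'   across VPs by construction.
#' @export
step_vp <- function(ensemble, geometry, tables = default_tables(), step = 1) {
  n <- nrow(ensemble)
  if (is.null(ensemble$alive)) ensemble$alive <- TRUE
  dep <- vector("list", n)
  ops <- matrix(0L, n, 2, dimnames = list(NULL, c("lookups", "normals")))
  for (i in seq_len(n)) {
    if (!ensemble$alive[i]) next
    if (ensemble$energy[i] < 1) {
      dep[[i]] <- data.frame(x = ensemble$x[i], y = ensemble$y[i],
                             z = ensemble$z[i],
                             edep = ensemble$energy[i] * ensemble$weight[i])
      ensemble$energy[i] <- 0
      ensemble$alive[i] <- FALSE
      next
    }
    lab <- classify_point(geometry, ensemble$x[i], ensemble$y[i], ensemble$z[i])
    r <- 1
    tab <- switch(as.character(lab),
                  air = air_tables(), opening = air_tables(),
                  brass = tables$brass, shifter = tables$water,
                  phantom = { r <- attr(lab, "rsp"); tables$water })
    E <- ensemble$energy[i]
    # identical operation sequence for every VP: 4 lookups, 3 normal draws
    de_mean <- lookup(tab, E, "dedx") * r * step
    de_sig <- lookup(tab, E, "strag") * sqrt(r * step)
    th_sig <- lookup(tab, E, "ang") * sqrt(r * step)
    lookup(tab, E, "nucl")
    draws <- rnorm(3)
    ops[i, ] <- c(4L, 3L)
    dE <- min(max(de_mean + de_sig * draws[1], 0), E)
    u <- .deflect_r(c(ensemble$ux[i], ensemble$uy[i], ensemble$uz[i]),
                    th_sig * draws[2], th_sig * draws[3])
    if (dE > 0) {
      dep[[i]] <- data.frame(
        x = ensemble$x[i] + 0.5 * step * ensemble$ux[i],
        y = ensemble$y[i] + 0.5 * step * ensemble$uy[i],
        z = ensemble$z[i] + 0.5 * step * ensemble$uz[i],
        edep = dE * ensemble$weight[i])
    }
    ensemble$energy[i] <- E - dE
    ensemble$x[i] <- ensemble$x[i] + step * ensemble$ux[i]
    ensemble$y[i] <- ensemble$y[i] + step * ensemble$uy[i]
    ensemble$z[i] <- ensemble$z[i] + step * ensemble$uz[i]
    ensemble$ux[i] <- u[1]; ensemble$uy[i] <- u[2]; ensemble$uz[i] <- u[3]
    if (ensemble$type[i] == 0 && ensemble$z[i] <= ensemble$deact_z[i]) {
      ensemble$alive[i] <- FALSE
    }
  }
  deps <- Filter(Negate(is.null), dep)
  structure(ensemble,
            deposits = if (length(deps)) do.call(rbind, deps) else
              data.frame(x = numeric(), y = numeric(), z = numeric(),
                         edep = numeric()),
            ops = ops)
}
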