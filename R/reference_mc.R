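# Single-history condensed-history transport in R.
#
# This is the readable, per-history statement of the reference engine's
# update rule; the batch engine in mc_simulate() runs the same rule in
# compiled code. Tests use it to pin down per-step semantics and to
# cross-check the compiled kernel.

#' Particle state
#'
#' @param position Numeric (x, y, z) in mm.
#' @param direction Unit vector; normalized on construction.
#' @param energy Kinetic energy in MeV (>= 0).
#' @param weight Statistical weight (> 0).
#' @param generation `"primary"` or `"secondary"`.
#' @return A `vpmc_particle`.
#' @export
particle_state <- function(position, direction, energy, weight = 1,
                           generation = c("primary", "secondary")) {
  generation <- match.arg(generation)
  n <- sqrt(sum(direction^2))
  if (n == 0) stop("direction must be nonzero")
  if (energy < 0) stop("energy must be >= 0")
  if (weight <= 0) stop("weight must be > 0")
  structure(list(position = as.numeric(position),
                 direction = as.numeric(direction) / n,
                 energy = energy, weight = weight, generation = generation,
                 alive = TRUE),
            class = "vpmc_particle")
}

.deflect_r <- function(u, t1, t2) {
  a <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- c(u[2] * a[3] - u[3] * a[2], u[3] * a[1] - u[1] * a[3],
          u[1] * a[2] - u[2] * a[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  v <- u + t1 * e1 + t2 * e2
  v / sqrt(sum(v^2))
}

.plane_below <- function(geometry, z) {
  ph <- geometry$phantom
  planes <- c(ph$origin[3] - ph$spacing[3] / 2,
              ph$origin[3] + (ph$dims[3] - 0.5) * ph$spacing[3])
  if (!is.null(geometry$aperture)) {
    planes <- c(planes, geometry$aperture$distal_z, geometry$aperture$proximal_z)
  }
  if (!is.null(geometry$shifter)) {
    planes <- c(planes, geometry$shifter$z0, geometry$shifter$z1)
  }
  planes <- sort(planes[planes < z - 1e-9], decreasing = TRUE)
  if (length(planes) == 0) -Inf else planes[1]
}

#' Transport one history with the reference engine's update rule
#'
#' Advances a particle through the beamline in condensed-history steps of at
#' most `step` mm (never straddling an axial component boundary), sampling
#' energy loss, straggling and deflection from the material tables, until the
#' energy falls below the 1 MeV cutoff (residual energy deposited locally) or
#' the particle exits. A nuclear event removes the primary, deposits part of
#' its energy locally and returns a secondary proton state for recursive
#' transport.
#'
#' @param state A [particle_state()]. Uses R's RNG (seed with `set.seed()`).
#' @param geometry A [beamline_geometry()].
#' @param tables Named list with `water` and `brass` tables.
#' @param nuclear Enable nuclear removal (primaries only).
#' @param step Maximum step length (mm).
#' @param max_steps Safety cap; exceeding it is a runaway-particle error.
#' @return List with `deposits` (data frame `x`, `y`, `z`, `edep`, `voxel`;
#'   `voxel` is `NA` outside the phantom grid) and `secondaries` (list of
#'   `vpmc_particle`).
#' @export
transport_history <- function(state, geometry, tables = default_tables(),
                              nuclear = TRUE, step = 1, max_steps = 20000) {
  stopifnot(inherits(state, "vpmc_particle"))
  if (!state$alive) stop("particle is not alive")
  ph <- geometry$phantom
  zlo <- ph$origin[3] - ph$spacing[3] / 2
  pos <- state$position; u <- state$direction
  E <- state$energy; w <- state$weight
  dep <- list(); secs <- list(); nstep <- 0
  voxel_of <- function(p) {
    i <- round((p - ph$origin) / ph$spacing) + 1
    if (all(i >= 1) && all(i <= ph$dims)) {
      i[1] + ph$dims[1] * ((i[2] - 1) + ph$dims[2] * (i[3] - 1))
    } else NA_integer_
  }
  put <- function(p, e) {
    dep[[length(dep) + 1]] <<- data.frame(x = p[1], y = p[2], z = p[3],
                                          edep = e, voxel = voxel_of(p))
  }
  repeat {
    nstep <- nstep + 1
    if (nstep > max_steps) {
      stop(sprintf("runaway particle after %d steps: E=%.3f MeV at (%.1f, %.1f, %.1f)",
                   max_steps, E, pos[1], pos[2], pos[3]))
    }
    if (E < 1) { if (E > 0) put(pos, E * w); break }
    if (pos[3] <= zlo + 1e-9 || u[3] >= -1e-6) break
    lab <- classify_point(geometry, pos[1], pos[2], pos[3])
    pb <- .plane_below(geometry, pos[3])
    smax <- (pb - pos[3]) / u[3]
    if (lab %in% c("air", "opening")) {
      if (!is.finite(smax)) break
      pos <- pos + (smax + 1e-6) * u
      next
    }
    s <- max(min(step, smax + 1e-6), 1e-6)
    if (lab == "brass") { tab <- tables$brass; r <- 1 }
    else if (lab == "shifter") { tab <- tables$water; r <- 1 }
    else { tab <- tables$water; r <- attr(lab, "rsp") }
    dE <- lookup(tab, E, "dedx") * r * s +
      lookup(tab, E, "strag") * sqrt(r * s) * rnorm(1)
    dE <- min(max(dE, 0), E)
    put(pos + 0.5 * s * u, dE * w)
    E <- E - dE
    th <- lookup(tab, E + dE, "ang") * sqrt(r * s)
    u <- .deflect_r(u, th * rnorm(1), th * rnorm(1))
    pos <- pos + s * u
    if (nuclear && state$generation == "primary") {
      pn <- lookup(tab, E + dE, "nucl") * r * s
      if (pn > 0 && runif(1) < pn) {
        Es <- 0.5 * E
        put(pos, (E - Es) * w)
        sd2 <- particle_state(pos, .deflect_r(u, 0.2 * rnorm(1), 0.2 * rnorm(1)),
                              Es, w, "secondary")
        secs[[length(secs) + 1]] <- sd2
        break
      }
    }
  }
  list(deposits = if (length(dep)) do.call(rbind, dep) else
         data.frame(x = numeric(), y = numeric(), z = numeric(),
                    edep = numeric(), voxel = integer()),
       secondaries = secs)
}
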