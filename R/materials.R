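# Material models and pre-computed physics tables.
#
# All lengths are mm, energies MeV, densities g/cm^3. Stopping powers are
# returned as linear stopping power (MeV/mm) in the actual material, i.e.
# mass stopping power times density.

.bethe_K <- 0.307075      # MeV cm^2 / mol
.me_c2 <- 0.51099895      # electron rest energy, MeV
.mp_c2 <- 938.27208816    # proton rest energy, MeV
.E_cutoff <- 1.0          # transport cutoff, MeV
.E_valid <- c(1, 250)     # validity range of the analytic formulas, MeV
.nuclear_E_threshold <- 20    # MeV, below which nuclear removal is off
.nuclear_sigma_water <- 0.001 # per mm of water: ~1% primary removal per cm

#' Define a material for proton transport
#'
#' A material is characterized by its density, elemental composition, mean
#' excitation energy and radiation length; these feed the Bethe stopping
#' power, Bohr straggling, Highland scattering and nuclear-removal models.
#'
#' @param name Material name.
#' @param density Mass density in g/cm^3.
#' @param composition Data frame with columns `Z`, `A`, `frac` (mass
#'   fractions; must sum to 1).
#' @param I_ev Mean excitation energy in eV.
#' @param X0 Radiation length in g/cm^2.
#' @param rsp Relative (to water) stopping power. Computed from the Bethe
#'   formula at 150 MeV when omitted; water is defined to have `rsp = 1`.
#' @return An object of class `vpmc_material`.
#' @export
#' @examples
#' w <- water_material()
#' stopping_power(w, 100)
material_spec <- function(name, density, composition, I_ev, X0, rsp = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.data.frame(composition) ||
      !all(c("Z", "A", "frac") %in% names(composition))) {
    stop("composition must be a data frame with columns Z, A, frac")
  }
  if (abs(sum(composition$frac) - 1) > 1e-9) {
    stop("mass fractions must sum to 1 (got ", sum(composition$frac), ")")
  }
  if (density <= 0) stop("density must be > 0")
  if (I_ev <= 0) stop("mean excitation energy I must be > 0")
  za <- sum(composition$frac * composition$Z / composition$A)
  m <- structure(
    list(name = name, density = density, composition = composition,
         I_ev = I_ev, X0 = X0, za = za, rsp = NA_real_),
    class = "vpmc_material")
  if (identical(name, "water")) {
    m$rsp <- 1
  } else if (is.null(rsp)) {
    m$rsp <- .bethe_linear(m, 150) / .bethe_linear(.water_spec(), 150)
  } else {
    m$rsp <- rsp
  }
  m
}

.water_spec <- function() {
  structure(
    list(name = "water", density = 1.0,
         composition = data.frame(Z = c(1, 8), A = c(1.008, 15.999),
                                  frac = c(0.1119, 0.8881)),
         I_ev = 75, X0 = 36.08,
         za = 0.1119 * 1 / 1.008 + 0.8881 * 8 / 15.999, rsp = 1),
    class = "vpmc_material")
}

#' Built-in materials
#'
#' `water_material()` is liquid water (I = 75 eV). `brass_material()` is
#' cartridge brass, Cu 70% / Zn 30% by mass at 8.50 g/cm^3 (the alloy of the
#' 30 mm collimating aperture blocks). `rangeshifter_material()` models the
#' ABS-resin range shifter as water: the shifter is specified by its water
#' equivalent thickness, so a water slab of that physical thickness is the
#' exact equivalent geometry.
#'
#' @return A `vpmc_material`.
#' @export
water_material <- function() .water_spec()

#' @rdname water_material
#' @export
brass_material <- function() {
  comp <- data.frame(Z = c(29, 30), A = c(63.546, 65.38), frac = c(0.70, 0.30))
  # log-mean excitation energy weighted by electron fraction (Bragg rule)
  za_i <- comp$frac * comp$Z / comp$A
  I_ev <- exp(sum(za_i * log(c(322, 330))) / sum(za_i))
  X0 <- 1 / sum(comp$frac / c(12.86, 12.43))
  material_spec("brass", 8.50, comp, I_ev, X0)
}

#' @rdname water_material
#' @export
rangeshifter_material <- function() {
  m <- .water_spec()
  m$name <- "rangeshifter"
  m
}

#' @export
print.vpmc_material <- function(x, ...) {
  cat(sprintf("<vpmc_material> %s: rho=%.3f g/cm^3, I=%.1f eV, X0=%.2f g/cm^2, RSP=%.3f\n",
              x$name, x$density, x$I_ev, x$X0, x$rsp))
  invisible(x)
}

.check_energy_range <- function(E, what) {
  if (any(E < .E_valid[1] | E > .E_valid[2])) {
    stop(sprintf("%s: energy outside validity range [%g, %g] MeV",
                 what, .E_valid[1], .E_valid[2]))
  }
}

# unrestricted electronic stopping power, MeV/mm (Bethe, no shell/density
# corrections -- adequate above ~1 MeV for the clinical range)
.bethe_linear <- function(material, E) {
  gamma <- 1 + E / .mp_c2
  beta2 <- 1 - 1 / gamma^2
  bg2 <- beta2 * gamma^2
  L <- log(2 * .me_c2 * 1e6 * bg2 / material$I_ev) - beta2
  s_mass <- .bethe_K * material$za / beta2 * L   # MeV cm^2/g
  s_mass * material$density / 10                 # MeV/mm
}

#' Proton stopping power
#'
#' Unrestricted electronic stopping power from the Bethe formula (no shell or
#' density corrections), times the material density: MeV per mm of the actual
#' material. Strictly decreasing with energy on the clinical range.
#'
#' @param material A [material_spec()].
#' @param E Kinetic energy in MeV, within \[1, 250\]. Vectorized.
#' @return Linear stopping power in MeV/mm.
#' @export
stopping_power <- function(material, E) {
  .check_energy_range(E, "stopping_power")
  .bethe_linear(material, E)
}

#' Continuous-slowing-down (CSDA) range
#'
#' Range in mm obtained by numerically integrating the reciprocal stopping
#' power from a 1 MeV cutoff up to `E`. Strictly increasing with energy.
#'
#' @inheritParams stopping_power
#' @return Range in mm (0 at the cutoff). Vectorized over `E`.
#' @export
csda_range <- function(material, E) {
  .check_energy_range(E, "csda_range")
  vapply(E, function(e) {
    if (e <= .E_cutoff) return(0)
    r <- tryCatch(
      integrate(function(x) 1 / .bethe_linear(material, x),
                lower = .E_cutoff, upper = e, rel.tol = 1e-9),
      error = function(err) err)
    if (inherits(r, "error")) {
      stop("csda_range: non-convergent integration for E = ", e,
           " MeV in ", material$name, ": ", conditionMessage(r))
    }
    r$value
  }, numeric(1))
}

#' Highest energy fully stopped by a material slab
#'
#' Inverts [csda_range()] by bisection: the largest energy whose CSDA range
#' does not exceed `thickness`. For the 30 mm brass aperture block this is
#' about 155 MeV, which is why the block stops all clinical energies used for
#' shallow intracranial targets.
#'
#' @param material A [material_spec()].
#' @param thickness Slab thickness in mm (>= 0).
#' @return Energy in MeV. If even 250 MeV is stopped, returns 250 with
#'   attribute `saturated = TRUE`.
#' @export
max_stopped_energy <- function(material, thickness) {
  if (thickness < 0) stop("thickness must be >= 0")
  if (thickness == 0) return(.E_cutoff)
  if (csda_range(material, .E_valid[2]) <= thickness) {
    return(structure(.E_valid[2], saturated = TRUE))
  }
  uniroot(function(e) csda_range(material, e) - thickness,
          interval = c(.E_cutoff, .E_valid[2]), tol = 1e-4)$root
}

#' Highland multiple-Coulomb-scattering angle
#'
#' Angular standard deviation (projected, radians) of the Highland
#' parameterization for a step of `step` mm. The logarithmic correction is
#' evaluated once at a 1 mm reference step and frozen, so sigma obeys exact
#' sqrt(step) scaling — this keeps per-step sampling consistent between the
#' VP and reference engines regardless of their step subdivision.
#'
#' @inheritParams stopping_power
#' @param step Step length in mm (> 0).
#' @return Angular sigma in rad.
#' @export
highland_sigma <- function(material, E, step) {
  .check_energy_range(E, "highland_sigma")
  if (any(step <= 0)) stop("step must be > 0")
  gamma <- 1 + E / .mp_c2
  pv <- (E^2 + 2 * E * .mp_c2) / (E + .mp_c2)  # momentum * velocity, MeV
  x_ref <- material$density * 0.1              # 1 mm reference, g/cm^2
  corr <- 1 + log10(x_ref / material$X0) / 9
  x <- material$density * step / 10
  14.1 / pv * sqrt(x / material$X0) * corr
}

#' Energy-straggling sigma (Bohr)
#'
#' Gaussian energy-loss straggling sigma for a step, from the Bohr variance
#' with the standard relativistic correction; scales as sqrt(step).
#'
#' @inheritParams highland_sigma
#' @return Sigma in MeV.
#' @export
straggling_sigma <- function(material, E, step) {
  .check_energy_range(E, "straggling_sigma")
  if (any(step < 0)) stop("step must be >= 0")
  gamma <- 1 + E / .mp_c2
  beta2 <- 1 - 1 / gamma^2
  var_per_cm <- 0.1569 * material$za * material$density *
    (1 - beta2 / 2) / (1 - beta2)
  sqrt(var_per_cm * step / 10)
}

#' Per-step nuclear interaction probability
#'
#' Simplified nuclear-removal model: an energy-independent macroscopic
#' cross-section above a 20 MeV threshold, scaled with density and normalized
#' so that about 1% of primaries are removed per cm of water at clinical
#' energies. First-order additive over sub-steps.
#'
#' @inheritParams highland_sigma
#' @return Removal probability for the step. Errors if it reaches 0.1 (step
#'   too large for the first-order model).
#' @export
nuclear_probability <- function(material, E, step) {
  .check_energy_range(E, "nuclear_probability")
  if (any(step < 0)) stop("step must be >= 0")
  p <- ifelse(E > .nuclear_E_threshold,
              .nuclear_sigma_water * material$density * step, 0)
  if (any(p >= 0.1)) {
    stop("nuclear_probability: step too large (probability >= 0.1); subdivide")
  }
  p
}

# ---- physics tables -------------------------------------------------------

#' Generate energy-indexed physics tables for one material
#'
#' The transport engines never evaluate the physics formulas in flight; they
#' query pre-computed tables of mean energy loss (MeV/mm), straggling sigma
#' (MeV/sqrt(mm)), deflection-angle sigma (rad/sqrt(mm)) and nuclear
#' interaction probability (1/mm) on a uniform energy grid. `analytic` mode
#' fills the tables from the closed-form models; `fitted` mode estimates them
#' from recorded condensed-history step samples (see
#' [record_material_histories()]), mirroring how a production engine fits its
#' tables from a full-physics reference code.
#'
#' @param material A [material_spec()].
#' @param energies Uniform energy grid in MeV; must cover \[0, 230\].
#' @param mode `"analytic"` or `"fitted"`.
#' @param histories For fitted mode: data frame from
#'   [record_material_histories()] with columns `energy`, `step`, `dE`,
#'   `dtheta`, `nuclear`.
#' @param min_per_bin Minimum history count per fitted energy bin.
#' @return A `vpmc_tables` object.
#' @export
generate_tables <- function(material, energies = seq(0, 230, by = 0.5),
                            mode = c("analytic", "fitted"),
                            histories = NULL, min_per_bin = 100) {
  mode <- match.arg(mode)
  if (min(energies) > 0 || max(energies) < 230) {
    stop("energy grid must cover [0, 230] MeV")
  }
  de <- diff(energies)
  if (any(de <= 0) || any(abs(de - de[1]) > 1e-9)) {
    stop("energy grid must be uniform and strictly increasing")
  }
  ecl <- pmin(pmax(energies, .E_cutoff), .E_valid[2])
  tab <- list(
    material = material$name, density = material$density,
    energy = energies,
    dedx = .bethe_linear(material, ecl),
    strag = straggling_sigma(material, ecl, 1),
    ang = highland_sigma(material, ecl, 1),
    nucl = ifelse(energies > .nuclear_E_threshold,
                  .nuclear_sigma_water * material$density, 0),
    mode = mode, seed = NA_integer_, n_histories = 0L)

  if (mode == "fitted") {
    if (is.null(histories)) stop("fitted mode requires recorded histories")
    eb <- sort(unique(histories$energy))
    counts <- vapply(eb, function(e) sum(histories$energy == e), numeric(1))
    if (any(counts < min_per_bin)) {
      stop("insufficient histories in fitted energy bins: ",
           paste(sprintf("%g MeV (n=%d)", eb[counts < min_per_bin],
                         as.integer(counts[counts < min_per_bin])),
                 collapse = ", "))
    }
    fit <- lapply(eb, function(e) {
      h <- histories[histories$energy == e, ]
      s <- h$step
      c(dedx = mean(h$dE / s),
        strag = sd(h$dE) / sqrt(mean(s)),
        ang = sd(h$dtheta) / sqrt(mean(s)),
        nucl = mean(h$nuclear) / mean(s))
    })
    fit <- do.call(rbind, fit)
    # calibrate the analytic shape by the history-derived ratios at the
    # fitted nodes (constant ratio beyond the outermost nodes), so table
    # invariants (e.g. monotone mean energy loss) carry over
    for (q in c("dedx", "strag", "ang", "nucl")) {
      at_nodes <- approx(energies, tab[[q]], xout = eb)$y
      ratio <- ifelse(at_nodes > 0, fit[, q] / at_nodes, 1)
      tab[[q]] <- tab[[q]] * approx(eb, ratio, xout = energies, rule = 2)$y
    }
    tab$n_histories <- nrow(histories)
    tab$seed <- attr(histories, "seed") %||% NA_integer_
  }
  tab <- structure(tab, class = "vpmc_tables")
  validate_tables(tab)
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Record condensed-history step samples in a uniform material
#'
#' Draws per-step outcomes (energy loss, projected deflection, nuclear flag)
#' with the reference engine's sampling rule at the requested energies,
#' producing the history bank that fitted-mode [generate_tables()] consumes.
#'
#' @param material A [material_spec()].
#' @param energies Energies (MeV) at which to record.
#' @param n_per_energy Histories per energy.
#' @param step Step length in mm.
#' @param seed RNG seed.
#' @return Data frame with columns `energy`, `step`, `dE`, `dtheta`,
#'   `nuclear`, carrying the seed as an attribute.
#' @export
record_material_histories <- function(material, energies, n_per_energy,
                                      step = 1, seed = 1L) {
  set.seed(seed)
  out <- lapply(energies, function(e) {
    dE <- .bethe_linear(material, e) * step +
      straggling_sigma(material, e, step) * rnorm(n_per_energy)
    dE <- pmax(dE, 0)
    dtheta <- highland_sigma(material, e, step) * rnorm(n_per_energy)
    nuc <- as.integer(runif(n_per_energy) < nuclear_probability(material, e, step))
    data.frame(energy = e, step = step, dE = dE, dtheta = dtheta, nuclear = nuc)
  })
  structure(do.call(rbind, out), seed = seed)
}

#' Validate physics-table invariants
#'
#' Checks that all entries are finite and non-negative, the energy grid is
#' strictly increasing, and the mean energy loss is strictly decreasing over
#' the machine energy span (71.3-228.8 MeV).
#'
#' @param tables A `vpmc_tables` object.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_tables <- function(tables) {
  for (q in c("dedx", "strag", "ang", "nucl")) {
    v <- tables[[q]]
    if (any(!is.finite(v)) || any(v < 0)) {
      stop("table column ", q, " has non-finite or negative entries")
    }
  }
  if (any(diff(tables$energy) <= 0)) stop("energy grid not strictly increasing")
  span <- tables$energy >= 71.3 & tables$energy <= 228.8
  if (any(diff(tables$dedx[span]) >= 0)) {
    stop("mean energy loss not strictly decreasing over the machine span")
  }
  invisible(TRUE)
}

#' Query a physics table
#'
#' Linear interpolation on the uniform energy grid; exact at grid nodes.
#' Energies outside the grid span are clamped to the nearest node with a
#' warning (straggling can carry an energy marginally out of range between
#' steps, which is benign).
#'
#' @param tables A `vpmc_tables` object.
#' @param E Energies in MeV. Vectorized.
#' @param quantity One of `"dedx"`, `"strag"`, `"ang"`, `"nucl"`.
#' @return Interpolated values.
#' @export
lookup <- function(tables, E, quantity = c("dedx", "strag", "ang", "nucl")) {
  quantity <- match.arg(quantity)
  eg <- tables$energy
  n <- length(eg)
  if (any(E < eg[1] | E > eg[n])) {
    warning("lookup: energy outside table span [", eg[1], ", ", eg[n],
            "] MeV; clamped")
    E <- pmin(pmax(E, eg[1]), eg[n])
  }
  de <- eg[2] - eg[1]
  t <- (E - eg[1]) / de
  i <- pmin(floor(t), n - 2)
  w <- t - i
  v <- tables[[quantity]]
  (1 - w) * v[i + 1] + w * v[i + 2]
}

# zero-valued tables used for air/opening so the uniform VP update rule can
# execute the same operation sequence in every material
air_tables <- function(energies = seq(0, 230, by = 0.5)) {
  structure(list(material = "air", density = 0, energy = energies,
                 dedx = numeric(length(energies)),
                 strag = numeric(length(energies)),
                 ang = numeric(length(energies)),
                 nucl = numeric(length(energies)),
                 mode = "analytic", seed = NA_integer_, n_histories = 0L),
            class = "vpmc_tables")
}

#' @export
print.vpmc_tables <- function(x, ...) {
  cat(sprintf("<vpmc_tables> %s (%s): %d energies in [%g, %g] MeV\n",
              x$material, x$mode, length(x$energy),
              min(x$energy), max(x$energy)))
  invisible(x)
}
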