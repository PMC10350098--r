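# Scenario-based robust optimization of spot weights.

#' Build the robust-optimization scenario set
#'
#' Setup uncertainty is modelled by shifting the isocenter positively and
#' negatively along each cardinal axis by `setup` mm; range uncertainty by
#' scaling the phantom's relative stopping powers by +/- `range_pct` %.
#' Every shift is combined with every range scaling, plus one nominal
#' scenario: with the defaults (2 mm, 3%) that is 1 + 6 x 2 = 13 scenarios.
#' Zero inputs collapse the corresponding factor.
#'
#' @param setup Setup-shift magnitude in mm (>= 0).
#' @param range_pct Range-scaling magnitude in % (>= 0).
#' @return A `vpmc_scenarios`: data frame with `sx`, `sy`, `sz` (mm) and
#'   `rsp_scale`, first row nominal.
#' @export
build_scenarios <- function(setup = 2, range_pct = 3) {
  if (setup < 0 || range_pct < 0) stop("setup and range_pct must be >= 0")
  shifts <- if (setup > 0) {
    rbind(c(setup, 0, 0), c(-setup, 0, 0), c(0, setup, 0),
          c(0, -setup, 0), c(0, 0, setup), c(0, 0, -setup))
  } else matrix(numeric(0), ncol = 3)
  scales <- if (range_pct > 0) c(1 + range_pct / 100, 1 - range_pct / 100) else 1
  rows <- list(data.frame(sx = 0, sy = 0, sz = 0, rsp_scale = 1))
  if (nrow(shifts) > 0) {
    for (f in scales) {
      rows[[length(rows) + 1]] <-
        data.frame(sx = shifts[, 1], sy = shifts[, 2], sz = shifts[, 3],
                   rsp_scale = f)
    }
  } else if (range_pct > 0) {
    rows[[2]] <- data.frame(sx = 0, sy = 0, sz = 0, rsp_scale = scales)
  }
  sc <- do.call(rbind, rows)
  rownames(sc) <- NULL
  class(sc) <- c("vpmc_scenarios", class(sc))
  sc
}

#' Apply an uncertainty scenario to a beamline
#'
#' An isocenter shift of the patient is implemented as the equivalent rigid
#' translation of the beamline relative to the fixed phantom (spot lateral
#' positions and component axial positions move by the negative shift), so
#' phantom-frame structure masks stay valid. Range scaling multiplies the
#' phantom's relative stopping powers.
#'
#' @param geometry A [beamline_geometry()].
#' @param spots A [spot_list()].
#' @param scenario One row of [build_scenarios()].
#' @return List with shifted `geometry` and `spots`.
#' @export
apply_scenario <- function(geometry, spots, scenario) {
  if (!all(is.finite(c(scenario$sx, scenario$sy, scenario$sz,
                       scenario$rsp_scale)))) {
    stop("scenario must have finite shift components and rsp_scale")
  }
  g <- geometry
  s <- spots
  s$x <- s$x - scenario$sx
  s$y <- s$y - scenario$sy
  dz <- -scenario$sz
  if (!is.null(g$aperture)) {
    g$aperture$distal_z <- g$aperture$distal_z + dz
    g$aperture$proximal_z <- g$aperture$proximal_z + dz
  }
  if (!is.null(g$shifter)) {
    g$shifter$z0 <- g$shifter$z0 + dz
    g$shifter$z1 <- g$shifter$z1 + dz
  }
  g$source_z <- g$source_z + dz
  g$phantom$values <- g$phantom$values * scenario$rsp_scale
  list(geometry = g, spots = s)
}

#' Per-scenario dose influence matrices
#'
#' For each scenario, runs one Monte Carlo simulation per spot at unit
#' weight and stores the dose restricted to the optimization region as a
#' column of a sparse matrix (rows = region voxels, columns = spots). Entries
#' below `prune` times the matrix maximum are dropped; a warning reports the
#' realized pruned fraction if it exceeds 5% of the matrix mass. Dose of any
#' weight vector is then the matrix product, within Monte Carlo noise.
#'
#' @param spots A [spot_list()].
#' @param geometry A [beamline_geometry()].
#' @param scenarios A [build_scenarios()] data frame.
#' @param region Logical array over the phantom grid: the optimization
#'   region (targets plus margins and any OAR shells).
#' @param engine `"vp"` or `"reference"`.
#' @param n_per_spot Histories per spot and scenario.
#' @param seed Integer seed.
#' @param prune Relative pruning threshold.
#' @param batches Batches per spot run (the per-entry standard errors are
#'   estimated across them).
#' @param tables Physics tables.
#' @return List of class `vpmc_influence`: `matrices` (one `dgCMatrix` per
#'   scenario), `ses` (matching standard-error matrices), `region` (voxel
#'   indices), `spots`, `scenarios`, `prune`.
#' @export
influence_matrices <- function(spots, geometry, scenarios, region,
                               engine = c("vp", "reference"),
                               n_per_spot = 2000, seed = 1, prune = 1e-4,
                               batches = 2, tables = default_tables()) {
  engine <- match.arg(engine)
  if (is.null(region) || !any(region)) stop("optimization region mask required")
  sim <- if (engine == "vp") vp_simulate else mc_simulate
  ridx <- which(region)
  mats <- ses <- vector("list", nrow(scenarios))
  for (s in seq_len(nrow(scenarios))) {
    sc <- apply_scenario(geometry, spots, scenarios[s, ])
    cols <- secols <- vector("list", nrow(spots))
    for (j in seq_len(nrow(spots))) {
      one <- sc$spots[j, ]
      one$weight <- 1
      d <- sim(one, sc$geometry, tables = tables, n_histories = n_per_spot,
               seed = seed + 1000L * s + j, batches = batches)
      cols[[j]] <- d$values[ridx]
      se <- d$values * ifelse(is.na(d$relse), 0, d$relse)
      secols[[j]] <- se[ridx]
    }
    M <- do.call(cbind, cols)
    S <- do.call(cbind, secols)
    thr <- prune * max(M)
    mass <- sum(M)
    S[M < thr] <- 0
    M[M < thr] <- 0
    lost <- 1 - sum(M) / mass
    if (lost > 0.05) {
      warning(sprintf("influence-matrix pruning removed %.1f%% of matrix mass",
                      100 * lost))
    }
    mats[[s]] <- methods::as(Matrix::Matrix(M, sparse = TRUE), "CsparseMatrix")
    ses[[s]] <- methods::as(Matrix::Matrix(S, sparse = TRUE), "CsparseMatrix")
  }
  structure(list(matrices = mats, ses = ses, region = ridx, spots = spots,
                 scenarios = scenarios, prune = prune, engine = engine),
            class = "vpmc_influence")
}

#' Dose-volume constraint
#'
#' @param kind `"V100"`, `"Dmin"`, `"CI"` or `"RHI"`.
#' @param soft,hard Soft ("better") and hard ("must") limits; the soft limit
#'   may not be stricter than the hard limit in the constraint direction.
#' @param direction `">="` (target coverage) or `"<="` (upper limit).
#' @param weight Penalty weight.
#' @return A `vpmc_dvc`.
#' @export
dvc <- function(kind = c("V100", "Dmin", "CI", "RHI"), soft, hard = soft,
                direction = c(">=", "<="), weight = 1) {
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  ok <- if (direction == ">=") soft >= hard else soft <= hard
  if (!ok) stop("soft limit must not be stricter than the hard limit")
  structure(list(kind = kind, soft = soft, hard = hard,
                 direction = direction, weight = weight), class = "vpmc_dvc")
}

#' Default target constraints
#'
#' The institutional-protocol target constraint set: V100 >= 99%,
#' Dmin >= 90%, CI100 <= 1.5~2.0, RHI100 <= 1.3~1.4.
#' @return List of [dvc()] objects.
#' @export
default_dvcs <- function() {
  list(dvc("V100", 99, 99, ">=", weight = 10),
       dvc("Dmin", 90, 90, ">=", weight = 10),
       dvc("CI", 1.5, 2.0, "<="),
       dvc("RHI", 1.3, 1.4, "<="))
}

# one-sided quadratic penalty surrogates per DVC kind, evaluated on the
# region dose vector of one scenario
.dvc_penalty <- function(d, target_rows, p, dv, grad = FALSE) {
  if (dv$kind %in% c("V100", "Dmin")) {
    # aim 5% above the coverage level to buy margin against the worst case
    lvl <- 1.05 * (if (dv$kind == "V100") p else dv$soft / 100 * p)
    r <- pmax(lvl - d[target_rows], 0)
    val <- dv$weight * mean(r^2) / p^2
    if (!grad) return(val)
    g <- numeric(length(d))
    g[target_rows] <- -2 * dv$weight * r / length(target_rows) / p^2
    list(value = val, grad = g)
  } else if (dv$kind == "RHI") {
    lvl <- dv$soft * p  # push max dose below the soft homogeneity limit
    r <- pmax(d[target_rows] - lvl, 0)
    val <- dv$weight * mean(r^2) / p^2
    if (!grad) return(val)
    g <- numeric(length(d))
    g[target_rows] <- 2 * dv$weight * r / length(target_rows) / p^2
    list(value = val, grad = g)
  } else {  # CI: suppress prescription-level dose outside the target
    out <- setdiff(seq_along(d), target_rows)
    lvl <- 0.8 * p
    r <- pmax(d[out] - lvl, 0)
    val <- dv$weight * mean(r^2) / p^2
    if (!grad) return(val)
    g <- numeric(length(d))
    g[out] <- 2 * dv$weight * r / length(out) / p^2
    list(value = val, grad = g)
  }
}

#' Worst-case robust optimization of spot weights
#'
#' Minimizes a worst-case composite objective over nonnegative spot weights:
#' each dose-volume constraint contributes a one-sided quadratic penalty
#' evaluated on its own worst scenario (for coverage constraints the
#' lowest-coverage scenario; for upper limits the highest-violation
#' scenario). The solver is projected gradient descent with Armijo
#' backtracking, so the objective is non-increasing over accepted iterations
#' and weights stay nonnegative by projection. In single-field optimization
#' (SFO) the coverage penalties are applied per field to each field's own
#' dose (scaled to its share of the prescription); multi-field optimization
#' (MFO) applies them to the summed dose only.
#'
#' @param influence A [influence_matrices()] result.
#' @param target Logical array/vector: target voxels (SOI), either over the
#'   phantom grid or over the region rows.
#' @param prescription Prescription dose in the influence matrices' units.
#' @param dvcs List of [dvc()] constraints.
#' @param mode `"SFO"` or `"MFO"`.
#' @param fields Integer field label per spot (for SFO with several fields).
#' @param iterations Maximum accepted iterations.
#' @param w0 Initial weights (default uniform).
#' @return List with `weights`, `objective` (trace over accepted iterations),
#'   `converged`, and `violated` (hard-limit report from the nominal and
#'   worst scenarios).
#' @export
optimize_weights <- function(influence, target, prescription,
                             dvcs = default_dvcs(), mode = c("SFO", "MFO"),
                             fields = NULL, iterations = 300, w0 = NULL) {
  mode <- match.arg(mode)
  mats <- influence$matrices
  ns <- length(mats)
  nspot <- ncol(mats[[1]])
  target <- as.logical(target)
  trows <- if (length(target) == nrow(mats[[1]])) which(target)
           else which(target[influence$region])
  if (length(trows) == 0) stop("target has no voxels inside the region")
  if (is.null(fields)) fields <- rep(1L, nspot)
  fl <- unique(fields)
  p <- prescription

  obj_grad <- function(w) {
    doses <- lapply(mats, function(A) as.numeric(A %*% w))
    total <- 0
    grad <- numeric(nspot)
    for (dv in dvcs) {
      per_field <- mode == "SFO" && dv$direction == ">=" && length(fl) > 1
      if (per_field) {
        for (f in fl) {
          wi <- w * (fields == f)
          df <- lapply(mats, function(A) as.numeric(A %*% wi))
          vals <- vapply(df, function(d)
            .dvc_penalty(d * length(fl), trows, p, dv), numeric(1))
          s <- which.max(vals)
          pg <- .dvc_penalty(df[[s]] * length(fl), trows, p, dv, grad = TRUE)
          total <- total + pg$value
          g <- as.numeric(Matrix::crossprod(mats[[s]], pg$grad)) * length(fl)
          grad <- grad + g * (fields == f)
        }
      } else {
        vals <- vapply(doses, function(d) .dvc_penalty(d, trows, p, dv),
                       numeric(1))
        s <- which.max(vals)
        pg <- .dvc_penalty(doses[[s]], trows, p, dv, grad = TRUE)
        total <- total + pg$value
        grad <- grad + as.numeric(Matrix::crossprod(mats[[s]], pg$grad))
      }
    }
    list(value = total, grad = grad)
  }

  w <- if (is.null(w0)) rep(1, nspot) else w0
  og <- obj_grad(w)
  trace <- og$value
  if (og$value == 0) {
    return(list(weights = w, objective = trace, converged = TRUE,
                violated = character(0)))
  }
  alpha <- 1 / max(abs(og$grad), 1e-12)
  for (it in seq_len(iterations)) {
    accepted <- FALSE
    for (ls in 1:30) {
      w_new <- pmax(w - alpha * og$grad, 0)
      og_new <- obj_grad(w_new)
      if (og_new$value <= og$value - 1e-4 * sum(og$grad * (w - w_new))) {
        accepted <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!accepted) break
    w <- w_new
    og <- og_new
    trace <- c(trace, og$value)
    alpha <- alpha * 1.8
    if (og$value < 1e-14 ||
        (length(trace) > 5 && abs(diff(tail(trace, 2))) < 1e-12 * trace[1])) {
      break
    }
  }

  ev <- evaluate_robust(w, influence, target, prescription)
  nominal <- ev[1, ]  # hard limits are reported against the nominal plan
  violated <- character(0)
  for (dv in dvcs) {
    val <- switch(dv$kind, V100 = nominal$V100, Dmin = nominal$Dmin,
                  CI = nominal$CI100, RHI = nominal$RHI100)
    bad <- if (dv$direction == ">=") val < dv$hard else val > dv$hard
    if (bad) violated <- c(violated, sprintf("%s %s %g (got %.3g)",
                                             dv$kind, dv$direction, dv$hard, val))
  }
  list(weights = w, objective = trace, converged = length(violated) == 0,
       violated = violated)
}

#' Per-scenario and worst-case plan index table
#'
#' Applies [plan_indices()] to every scenario's dose (influence matrix times
#' the weights) and appends a worst-case row: the minimum over scenarios for
#' V100 and Dmin, the maximum for CI100 and RHI100.
#'
#' @param weights Nonnegative spot weights.
#' @param influence A [influence_matrices()] result.
#' @param target Target mask (phantom grid or region rows).
#' @param prescription Prescription dose.
#' @return Data frame: one row per scenario plus a `"worst"` row.
#' @export
evaluate_robust <- function(weights, influence, target, prescription) {
  target <- as.logical(target)
  trows <- if (length(target) == nrow(influence$matrices[[1]])) which(target)
           else which(target[influence$region])
  rows <- lapply(seq_along(influence$matrices), function(s) {
    d <- as.numeric(influence$matrices[[s]] %*% weights)
    m <- logical(length(d)); m[trows] <- TRUE
    pi <- plan_indices(d, m, prescription)
    data.frame(scenario = as.character(s), V100 = pi$V100, Dmin = pi$Dmin,
               CI100 = pi$CI100, RHI100 = pi$RHI100)
  })
  tab <- do.call(rbind, rows)
  worst <- data.frame(scenario = "worst", V100 = min(tab$V100),
                      Dmin = min(tab$Dmin), CI100 = max(tab$CI100),
                      RHI100 = max(tab$RHI100))
  rbind(tab, worst)
}
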