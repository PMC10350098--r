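# Independent oracles and shared fixtures.

# winding-number point-in-polygon oracle (independent of the crossing-number
# implementation), using the standard half-open edge convention so ties are
# resolved identically
winding_inside <- function(poly, x, y) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  vapply(seq_along(x), function(k) {
    wn <- 0L
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      is_left <- (px[j] - px[i]) * (y[k] - py[i]) -
        (x[k] - px[i]) * (py[j] - py[i])
      if (py[i] <= y[k]) {
        if (py[j] > y[k] && is_left > 0) wn <- wn + 1L
      } else {
        if (py[j] <= y[k] && is_left < 0) wn <- wn - 1L
      }
    }
    wn != 0L
  }, logical(1))
}

# random star-shaped (hence simple) polygon
random_simple_polygon <- function(nv = 12, rmin = 2, rmax = 10) {
  th <- sort(runif(nv, 0, 2 * pi))
  r <- runif(nv, rmin, rmax)
  cbind(r * cos(th), r * sin(th))
}

# brute-force gamma pass rate: dense offset lattice with no early
# termination. Offsets are capped just beyond one DTA because an offset with
# r > DTA cannot yield gamma <= 1, so pass/fail decisions are unaffected.
gamma_pass_oracle <- function(ref, eval, spacing, dd_pct = 2, dta = 2,
                              thr_pct = 10, h = dta / 4) {
  dims <- dim(ref)
  rmax <- max(ref)
  thr <- thr_pct / 100 * rmax
  dd <- dd_pct / 100 * rmax
  nmax <- ceiling(1.05 * dta / h)
  offs <- expand.grid(x = (-nmax:nmax) * h, y = (-nmax:nmax) * h,
                      z = (-nmax:nmax) * h)
  offs <- offs[offs$x^2 + offs$y^2 + offs$z^2 <= (1.05 * dta)^2, ]
  g2min <- array(Inf, dims)
  ax <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
  for (o in seq_len(nrow(offs))) {
    ov <- c(offs$x[o], offs$y[o], offs$z[o]) / spacing  # voxel units
    i0 <- floor(ov); fr <- ov - i0
    r2n <- sum((c(offs$x[o], offs$y[o], offs$z[o]) / dta)^2)
    # trilinear sample of `eval` at every voxel + constant offset
    samp <- array(0, dims)
    wsum <- array(0, dims)
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      w <- prod(ifelse(c(cx, cy, cz) == 1, fr, 1 - fr))
      if (w == 0) next
      sh <- i0 + c(cx, cy, cz)
      src <- list(ax[[1]] + sh[1], ax[[2]] + sh[2], ax[[3]] + sh[3])
      ok <- lapply(1:3, function(a) src[[a]] >= 1 & src[[a]] <= dims[a])
      dst <- lapply(1:3, function(a) ax[[a]][ok[[a]]])
      srci <- lapply(1:3, function(a) src[[a]][ok[[a]]])
      samp[dst[[1]], dst[[2]], dst[[3]]] <-
        samp[dst[[1]], dst[[2]], dst[[3]]] +
        w * eval[srci[[1]], srci[[2]], srci[[3]]]
      wsum[dst[[1]], dst[[2]], dst[[3]]] <-
        wsum[dst[[1]], dst[[2]], dst[[3]]] + w
    }
    full <- wsum > 1 - 1e-9  # voxels whose sample lies fully inside
    g2 <- ((samp - ref) / dd)^2 + r2n
    g2[!full] <- Inf
    g2min <- pmin(g2min, g2)
  }
  sel <- ref >= thr
  100 * mean(g2min[sel] <= 1 + 1e-9)
}

# smooth 3D test field
smooth_field <- function(dims, seed = 1) {
  set.seed(seed)
  f <- function(n) {
    x <- seq(0, 1, length.out = n)
    runif(1, 0.5, 1) * exp(-((x - runif(1, 0.3, 0.7)) / 0.3)^2) + 0.2
  }
  outer(outer(f(dims[1]), f(dims[2])), f(dims[3]))
}

# shoelace polygon area
polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

# ---- shared toy robust-planning fixture (built once per test run) --------
# APRS-free shallow SRS-like case: 9 mm radius (3.1 cc) water target at
# 50 mm depth, seven energy layers, spots on a 4 mm grid, patient-specific
# opening from the clinical margin recipe, 13 uncertainty scenarios.
toy_robust_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    w <- water_material()
    E_for_depth <- function(d) {
      uniroot(function(E) csda_range(w, E) - d, c(71.4, 160))$root
    }
    Es <- vapply(seq(46, 70, by = 3), E_for_depth, numeric(1))
    phantom <- water_box(lateral_half = 35, depth = 100, spacing = 2)
    target <- sphere_mask(phantom, c(0, 0, 50), 9)
    poly <- opening_from_target(target, phantom)
    geom <- beamline_geometry("AP", aperture_block(poly), phantom)
    g <- expand.grid(x = seq(-12, 12, 4), y = seq(-12, 12, 4))
    g <- g[g$x^2 + g$y^2 <= 169, ]
    spots <- spot_list(rep(Es, each = nrow(g)), rep(g$x, length(Es)),
                       rep(g$y, length(Es)))
    region <- sphere_mask(phantom, c(0, 0, 50), 17)
    infl <- influence_matrices(spots, geom, build_scenarios(), region,
                               engine = "vp", n_per_spot = 1500, seed = 42)
    d0 <- as.numeric(infl$matrices[[1]] %*% rep(1, nrow(spots)))
    presc <- median(d0[which(target[infl$region])])
    opt <- optimize_weights(infl, target, presc, iterations = 400)
    cache <<- list(geometry = geom, spots = spots, target = target,
                   region = region, influence = infl, prescription = presc,
                   optimum = opt, phantom = phantom)
    cache
  }
})
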