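# Material models and physics tables.

test_that("stopping power matches an independent Bethe evaluation and is monotone", {
  w <- water_material()
  # independent single-point evaluation of the Bethe formula, I = 75 eV
  E <- 100
  mp <- 938.27208816; me <- 0.51099895
  g <- 1 + E / mp; b2 <- 1 - 1 / g^2
  s_hand <- 0.307075 * 0.5551 / b2 *
    (log(2 * me * 1e6 * b2 * g^2 / 75) - b2) / 10  # MeV/mm at unit density
  expect_lt(abs(stopping_power(w, 100) - s_hand) / s_hand, 0.05)

  # strictly decreasing over the machine span
  Es <- seq(10, 230, by = 1)
  expect_true(all(diff(stopping_power(w, Es)) < 0))
  expect_true(all(diff(stopping_power(brass_material(), Es)) < 0))
  expect_gt(stopping_power(w, 71.3), stopping_power(w, 228.8))

  # brass-to-water stopping ratio approximates the brass RSP
  b <- brass_material()
  ratio <- stopping_power(b, 150) / stopping_power(w, 150)
  expect_lt(abs(ratio - b$rsp) / b$rsp, 0.1)

  expect_error(stopping_power(w, 0.5), "validity range")
  expect_error(stopping_power(w, 300), "validity range")
})

test_that("CSDA range integrates 1/S correctly and is invertible", {
  w <- water_material(); b <- brass_material()
  # refined-quadrature oracle: trapezoid at two resolutions
  trap <- function(m, E, n) {
    x <- seq(1, E, length.out = n)
    y <- 1 / stopping_power(m, x)
    sum((y[-1] + y[-n]) / 2 * diff(x))
  }
  r_pkg <- csda_range(w, 147)
  expect_lt(abs(r_pkg - trap(w, 147, 20001)) / r_pkg, 0.005)

  expect_equal(csda_range(w, 1), 0)
  Es <- seq(10, 230, by = 1)
  expect_true(all(diff(csda_range(w, Es)) > 0))
  expect_true(all(diff(csda_range(b, Es)) > 0))

  # 30 mm of brass stops protons up to about 155 MeV
  expect_lt(abs(csda_range(b, 155) - 30) / 30, 0.1)
  expect_lt(abs(max_stopped_energy(b, 30) - 155) / 155, 0.1)

  # round-trip identity within 0.1 MeV
  for (E in c(20, 120, 220)) {
    expect_lt(abs(max_stopped_energy(w, csda_range(w, E)) - E), 0.1)
  }
  expect_lte(max_stopped_energy(b, 0), 1)
  sat <- max_stopped_energy(w, 1000)
  expect_true(isTRUE(attr(sat, "saturated")))
})

test_that("Highland sigma scales as sqrt(step) and matches a hand evaluation", {
  w <- water_material(); b <- brass_material()
  s <- 0.5
  expect_lt(abs(highland_sigma(w, 120, 4 * s) / highland_sigma(w, 120, s) - 2),
            0.1)
  expect_gt(highland_sigma(b, 150, 1), highland_sigma(w, 150, 1))
  # independent Highland evaluation, water, 160 MeV, 1 mm
  E <- 160; mp <- 938.27208816
  pv <- (E^2 + 2 * E * mp) / (E + mp)
  x <- 0.1 / 36.08
  hand <- 14.1 / pv * sqrt(x) * (1 + log10(x) / 9)
  expect_lt(abs(highland_sigma(w, 160, 1) - hand) / hand, 0.1)
})

test_that("Bohr straggling sigma scales as sqrt(step) and matches a hand evaluation", {
  w <- water_material()
  expect_lt(abs(straggling_sigma(w, 150, 4) / straggling_sigma(w, 150, 1) - 2),
            0.02)
  # independent Bohr evaluation with relativistic factor
  E <- 150; mp <- 938.27208816
  g <- 1 + E / mp; b2 <- 1 - 1 / g^2
  hand <- sqrt(0.1569 * 0.5551 * 0.1 * (1 - b2 / 2) / (1 - b2))
  expect_lt(abs(straggling_sigma(w, 150, 1) - hand) / hand, 0.05)
  expect_equal(straggling_sigma(w, 150, 0), 0)
})

test_that("nuclear removal probability has threshold, additivity and sane totals", {
  w <- water_material()
  expect_equal(nuclear_probability(w, 10, 1), 0)
  s <- 0.5
  expect_lt(abs(nuclear_probability(w, 160, 2 * s) /
                  (2 * nuclear_probability(w, 160, s)) - 1), 0.02)
  expect_error(nuclear_probability(w, 160, 200), "too large")

  # engine-removal fraction vs the closed-form exponential oracle
  geom <- beamline_geometry("AP", NULL,
                            water_box(lateral_half = 20, depth = 200, spacing = 2))
  d <- mc_simulate(spot_list(160, 0, 0), geom, n_histories = 6000, seed = 3,
                   batches = 2)
  frac <- d$meta$n_secondaries / d$meta$n_primaries
  L <- csda_range(w, 160) - csda_range(w, 20)  # nuclear-active path length
  frac_oracle <- 1 - exp(-0.001 * L)
  expect_lt(abs(frac - frac_oracle) / frac_oracle, 0.2)
})

test_that("generate_tables covers the grid, is validated, and fitted mode converges", {
  w <- water_material()
  tw <- generate_tables(w)
  expect_equal(range(tw$energy), c(0, 230))
  span <- tw$energy >= 71.3 & tw$energy <= 228.8
  expect_true(all(diff(tw$dedx[span]) < 0))
  expect_error(generate_tables(w, energies = seq(50, 230, 0.5)), "cover")
  expect_error(generate_tables(w, mode = "fitted"), "histories")

  eb <- c(80, 150, 220)
  h5 <- record_material_histories(w, eb, 1e5, seed = 7)
  tf <- generate_tables(w, mode = "fitted", histories = h5)
  for (q in c("dedx", "strag", "ang")) {
    a <- lookup(tw, eb, q); f <- lookup(tf, eb, q)
    expect_lt(max(abs(f - a) / a), 0.05)
  }
  # convergence tightens with ten times the histories
  h6 <- record_material_histories(w, eb, 1e6, seed = 8)
  tf6 <- generate_tables(w, mode = "fitted", histories = h6)
  for (q in c("dedx", "strag", "ang")) {
    a <- lookup(tw, eb, q); f <- lookup(tf6, eb, q)
    expect_lt(max(abs(f - a) / a), 0.02)
  }
  expect_error(
    generate_tables(w, mode = "fitted",
                    histories = record_material_histories(w, eb, 50)),
    "insufficient histories")
})

test_that("table lookup is exact at nodes, linear between, and clamps outside", {
  tw <- generate_tables(water_material())
  expect_identical(lookup(tw, 100, "dedx"), tw$dedx[tw$energy == 100])
  mid <- (tw$dedx[tw$energy == 100] + tw$dedx[tw$energy == 100.5]) / 2
  expect_equal(lookup(tw, 100.25, "dedx"), mid)

  # 1000-energy sweep against an independent piecewise-linear evaluation
  set.seed(11)
  Es <- runif(1000, 0, 230)
  ora <- vapply(Es, function(e) {
    i <- min(floor((e - 0) / 0.5), length(tw$energy) - 2)
    wgt <- (e - 0) / 0.5 - i
    (1 - wgt) * tw$strag[i + 1] + wgt * tw$strag[i + 2]
  }, numeric(1))
  expect_identical(lookup(tw, Es, "strag"), ora)

  expect_warning(v <- lookup(tw, -3, "dedx"), "clamped")
  expect_identical(v, tw$dedx[1])
})

test_that("material construction enforces invariants", {
  expect_error(material_spec("x", 1, data.frame(Z = 1, A = 1, frac = 0.9),
                             75, 36), "sum to 1")
  expect_error(material_spec("x", -1, data.frame(Z = 1, A = 1, frac = 1),
                             75, 36), "density")
  expect_equal(water_material()$rsp, 1)
  b <- brass_material()
  expect_equal(sum(b$composition$frac), 1)
  expect_gt(b$rsp, 4)
})
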