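# Beamline geometry: crossing-number opening test, point classification,
# beam model, validation configs, phantoms, margin-derived openings.

test_that("crossing-number test classifies circle points and matches the winding oracle", {
  ap <- aperture_block(circle_polygon(5))
  expect_true(point_in_opening(ap, 0, 0))
  expect_false(point_in_opening(ap, 6, 0))

  set.seed(21)
  for (k in 1:50) {
    poly <- random_simple_polygon(nv = sample(5:20, 1))
    x <- runif(1000, -11, 11); y <- runif(1000, -11, 11)
    expect_identical(point_in_opening(poly, x, y), winding_inside(poly, x, y))
  }
  expect_error(point_in_opening(ap, Inf, 0), "finite")
})

test_that("near-edge points follow the documented half-open tie rule", {
  set.seed(22)
  for (k in 1:20) {
    poly <- random_simple_polygon(nv = 10)
    n <- nrow(poly)
    j <- c(2:n, 1)
    mx <- (poly[, 1] + poly[j, 1]) / 2
    my <- (poly[, 2] + poly[j, 2]) / 2
    ex <- poly[j, 1] - poly[, 1]; ey <- poly[j, 2] - poly[, 2]
    len <- sqrt(ex^2 + ey^2)
    # edge midpoints nudged 1e-6 mm to both sides along the edge normal
    for (s in c(1e-6, -1e-6)) {
      px <- mx - s * ey / len; py <- my + s * ex / len
      expect_identical(point_in_opening(poly, px, py),
                       winding_inside(poly, px, py))
    }
  }
})

test_that("degenerate polygons are rejected at construction", {
  expect_error(aperture_block(matrix(c(0, 0, 1, 1), 2, 2)), "degenerate")
  bow <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))  # self-intersecting
  expect_error(aperture_block(bow), "self-intersect")
  expect_error(aperture_block(circle_polygon(5), thickness = 0), "thickness")
})

test_that("classify_point applies the axial-slab then lateral tests", {
  geom <- beamline_geometry("APRS", aperture_block(circle_polygon(5)),
                            water_box(lateral_half = 30, depth = 100))
  expect_identical(as.character(classify_point(geom, 0, 0, 165)), "opening")
  expect_identical(as.character(classify_point(geom, 20, 0, 165)), "brass")
  expect_identical(as.character(classify_point(geom, 40, 0, 200)), "air")  # r=4cm > 3.05cm
  expect_identical(as.character(classify_point(geom, 10, 0, 200)), "shifter")
  ph <- classify_point(geom, 0, 0, 50)
  expect_identical(as.character(ph), "phantom")
  expect_equal(attr(ph, "rsp"), 1)
  expect_identical(as.character(classify_point(geom, 0, 0, 120)), "air")
  expect_error(classify_point(geom, NaN, 0, 0), "finite")
})

test_that("in-air sigma interpolates the machine beam model", {
  expect_equal(in_air_sigma(71.3), 5.0)
  expect_equal(in_air_sigma(228.8), 2.0)
  mid <- in_air_sigma((71.3 + 228.8) / 2)
  expect_true(mid > 2 && mid < 5)
  expect_error(in_air_sigma(60), "machine span")
  expect_length(machine_energies(), 97)
})

test_that("build_config lays out the energy-layer validation fields", {
  a <- build_config("A", 10)
  expect_equal(nrow(a$spots), 49)  # 2.5 mm lattice points with r <= 10 mm
  expect_true(all(a$spots$energy == 147.0))
  expect_null(a$geometry$shifter)
  expect_identical(a$geometry$machine, "AP")
  # block on the standard mount, 10 mm gap to the shifter in ConfigB
  expect_equal(a$geometry$aperture$distal_z, 150)
  b <- build_config("B", 20)
  expect_true(all(b$spots$energy == 161.5))
  expect_false(is.null(b$geometry$shifter))
  expect_equal(b$geometry$shifter$z0 - b$geometry$aperture$proximal_z, 10)
  expect_error(build_config("A", -1), "diameter")

  # builders are pure: identical inputs give identical geometry
  a2 <- build_config("A", 10)
  expect_identical(a$geometry, a2$geometry)
  expect_identical(a$spots, a2$spots)
})

test_that("phantom fixtures are deterministic and correctly structured", {
  wb <- water_box(lateral_half = 10, depth = 20)
  expect_true(all(wb$values == 1))
  si <- slab_insert_phantom(lateral_half = 10, depth = 80)
  expect_setequal(unique(as.numeric(si$values)), c(1, 1.6, 0.001))
  d <- 108 - grid_axis(si, 3)
  expect_true(all(si$values[, , d > 40 & d <= 50] == 1.6))
  expect_true(all(si$values[, , d > 60 & d <= 65] == 0.001))
  expect_identical(toy_head_phantom(), toy_head_phantom())
  expect_error(vpmc_grid(array(1, c(2, 2, 2)), c(0, 0, 0), c(1, 0, 1)),
               "spacing")
})

test_that("opening_from_target applies the PTV and block margins", {
  g <- water_box(lateral_half = 25, depth = 50, spacing = 1, surface_z = 25)
  m <- sphere_mask(g, c(0, 0, 0), 10)
  poly <- opening_from_target(m, g, ptv_margin = 1, block_margin = 2)
  expect_lt(abs(polygon_area(poly) - pi * 13^2) / (pi * 13^2), 0.05)
  poly0 <- opening_from_target(m, g, 0, 0)
  expect_lt(abs(polygon_area(poly0) - pi * 10^2) / (pi * 10^2), 0.05)

  # irregular two-lobe target: every projected voxel dilated by 3 mm is
  # contained in the polygon
  m2 <- sphere_mask(g, c(-6, 0, 0), 5) | sphere_mask(g, c(8, 3, 5), 4)
  poly2 <- opening_from_target(m2, g, 1, 2)
  idx <- which(apply(m2, c(1, 2), any), arr.ind = TRUE)
  cx <- grid_axis(g, 1)[idx[, 1]]; cy <- grid_axis(g, 2)[idx[, 2]]
  th <- 2 * pi * (0:7) / 8
  for (t in th) {
    expect_true(all(point_in_opening(poly2, cx + 2.99 * cos(t),
                                     cy + 2.99 * sin(t))))
  }
  expect_error(opening_from_target(m & FALSE, g), "empty")
})

test_that("beamline assembly rejects overlapping components", {
  ph <- water_box(lateral_half = 10, depth = 20)
  expect_error(
    beamline_geometry("APRS", aperture_block(circle_polygon(5), distal_z = 185),
                      ph),
    "overlap")
})
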