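# Beamline and phantom geometry.
#
# Coordinate convention: isocenter at the origin, the beam travels along -z
# from +z. The default clinical mount puts the aperture block's downstream
# face 150 mm from isocenter (block slab z in [150, 180] mm) and the range
# shifter's downstream face at 190 mm (slab [190, 235] mm, 45 mm water
# equivalent, 6.1 cm diameter), leaving a 10 mm gap between shifter and
# block. Grids are voxel-center addressed.

.machine_span <- c(71.3, 228.8)

#' A 3D voxel grid
#'
#' Shared container for relative-stopping-power phantoms and dose grids:
#' a 3D array with a voxel-center origin (mm) and per-axis spacing (mm).
#'
#' @param values 3D numeric array, indexed `[ix, iy, iz]` with z increasing
#'   with index (the beam enters at the highest-z slice).
#' @param origin Position (mm) of the center of voxel `[1, 1, 1]`.
#' @param spacing Voxel spacing per axis (mm).
#' @return A `vpmc_grid`.
#' @export
vpmc_grid <- function(values, origin, spacing) {
  if (length(dim(values)) != 3) stop("values must be a 3D array")
  if (any(spacing <= 0)) stop("spacing must be > 0")
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = as.numeric(spacing), dims = dim(values)),
            class = "vpmc_grid")
}

#' @export
print.vpmc_grid <- function(x, ...) {
  cat(sprintf("<vpmc_grid> %s voxels, spacing (%s) mm, origin (%s) mm\n",
              paste(x$dims, collapse = "x"),
              paste(x$spacing, collapse = ", "),
              paste(signif(x$origin, 5), collapse = ", ")))
  invisible(x)
}

#' Voxel-center coordinates along one axis
#' @param grid A `vpmc_grid`.
#' @param axis 1, 2 or 3.
#' @return Numeric vector of voxel-center positions (mm).
#' @export
grid_axis <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dims[axis]) - 1) * grid$spacing[axis]
}

#' Aperture block with a polygonal opening
#'
#' A brass collimating block of the given thickness whose patient-specific
#' opening is an arbitrary simple polygon in the plane perpendicular to the
#' beam axis. The block is laterally infinite outside the opening.
#'
#' @param polygon n x 2 matrix of (x, y) vertices in mm, ordered along the
#'   boundary; implicitly closed. Must be simple with >= 3 vertices.
#' @param thickness Block thickness in mm (default 30, which stops protons
#'   up to about 155 MeV).
#' @param distal_z z of the downstream face in mm (default 150: the
#'   applicator mount distance to isocenter).
#' @param material Block material (default brass).
#' @return A `vpmc_aperture`.
#' @export
aperture_block <- function(polygon, thickness = 30, distal_z = 150,
                           material = brass_material()) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2) stop("polygon must be an n x 2 matrix")
  # drop an explicit closing vertex
  n <- nrow(polygon)
  if (n >= 2 && all(polygon[1, ] == polygon[n, ])) polygon <- polygon[-n, , drop = FALSE]
  if (nrow(polygon) < 3) stop("degenerate polygon: need >= 3 distinct vertices")
  if (thickness <= 0) stop("thickness must be > 0")
  if (.polygon_self_intersects(polygon)) {
    stop("degenerate polygon: edges self-intersect")
  }
  structure(list(polygon = polygon, thickness = thickness,
                 distal_z = distal_z, proximal_z = distal_z + thickness,
                 material = material),
            class = "vpmc_aperture")
}

.polygon_self_intersects <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, p[c(2:n, 1), , drop = FALSE])  # x1 y1 x2 y2
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i || j == i %% n + 1 || i == j %% n + 1) next  # shared vertex
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- cross(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- cross(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- cross(b[1], b[2], b[3], b[4], a[3], a[4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Regular polygon approximating a circular opening
#'
#' Circular openings are represented as 64-gons by default; the inscribed
#' 64-gon underestimates the circle area by about 0.16%.
#'
#' @param radius Circle radius in mm.
#' @param n Number of vertices.
#' @param center Circle center (x, y) in mm.
#' @return n x 2 vertex matrix.
#' @export
circle_polygon <- function(radius, n = 64, center = c(0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

#' Crossing-number point-in-opening test
#'
#' Determines whether a lateral position is inside the aperture opening using
#' the crossing-number (ray casting) algorithm: a ray cast in +x from the
#' point crosses the polygon boundary an odd number of times if and only if
#' the point is inside. Edge and vertex ties are resolved by the standard
#' half-open rule (a vertex counts as a crossing iff its y strictly exceeds
#' the test point's y), so classification is deterministic everywhere.
#'
#' @param aperture A [aperture_block()] (or a bare n x 2 polygon matrix).
#' @param x,y Lateral coordinates in mm. Vectorized.
#' @return Logical vector: `TRUE` if inside the opening.
#' @export
point_in_opening <- function(aperture, x, y) {
  poly <- if (inherits(aperture, "vpmc_aperture")) aperture$polygon else as.matrix(aperture)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("coordinates must be finite")
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > y) != (py[j] > y)) &
      (x < px[j] + (y - py[j]) * (px[i] - px[j]) / (py[i] - py[j]))
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside
}

#' Assemble a beamline
#'
#' Combines machine type (AP: aperture only; APRS: aperture plus range
#' shifter), the aperture block, the phantom grid and the particle source
#' plane into one geometry object consumed by both transport engines.
#'
#' @param machine `"AP"` or `"APRS"`.
#' @param aperture A [aperture_block()], or `NULL` for an open beamline.
#' @param phantom A `vpmc_grid` of relative stopping powers.
#' @param shifter_distal_z Downstream face of the range shifter (mm).
#' @param shifter_wet Water equivalent thickness of the shifter (mm); the
#'   shifter is modelled as a water slab of this physical thickness.
#' @param shifter_diameter Shifter diameter (mm).
#' @param source_z z of the source plane (mm); must sit upstream of every
#'   component.
#' @return A `vpmc_beamline`.
#' @export
beamline_geometry <- function(machine = c("AP", "APRS"), aperture, phantom,
                              shifter_distal_z = 190, shifter_wet = 45,
                              shifter_diameter = 61, source_z = 250) {
  machine <- match.arg(machine)
  shifter <- NULL
  if (machine == "APRS") {
    shifter <- list(z0 = shifter_distal_z, z1 = shifter_distal_z + shifter_wet,
                    radius = shifter_diameter / 2)
  }
  ph_top <- phantom$origin[3] + (phantom$dims[3] - 0.5) * phantom$spacing[3]
  spans <- list(phantom = c(phantom$origin[3] - phantom$spacing[3] / 2, ph_top))
  if (!is.null(aperture)) spans$block <- c(aperture$distal_z, aperture$proximal_z)
  if (!is.null(shifter)) spans$shifter <- c(shifter$z0, shifter$z1)
  spans <- spans[order(vapply(spans, min, numeric(1)))]
  if (length(spans) > 1) {
    for (i in seq_len(length(spans) - 1)) {
      if (spans[[i]][2] > spans[[i + 1]][1] + 1e-9) {
        stop("component axial extents overlap: ", names(spans)[i], " and ",
             names(spans)[i + 1])
      }
    }
  }
  top <- max(vapply(spans, max, numeric(1)))
  if (source_z <= top) source_z <- top + 5
  structure(list(machine = machine, aperture = aperture, shifter = shifter,
                 phantom = phantom, source_z = source_z),
            class = "vpmc_beamline")
}

#' @export
print.vpmc_beamline <- function(x, ...) {
  cat(sprintf("<vpmc_beamline> machine %s%s%s, phantom %s voxels\n",
              x$machine,
              if (!is.null(x$aperture))
                sprintf(", block z[%g,%g]", x$aperture$distal_z, x$aperture$proximal_z)
              else "",
              if (!is.null(x$shifter))
                sprintf(", shifter z[%g,%g]", x$shifter$z0, x$shifter$z1)
              else "",
              paste(x$phantom$dims, collapse = "x")))
  invisible(x)
}

#' Classify a point in the beamline
#'
#' Axial-slab test first, then a lateral test: inside the block slab the
#' classification delegates to the crossing-number opening test; inside the
#' shifter slab an inside-radius test against the shifter diameter is used;
#' elsewhere the phantom grid is looked up (relative stopping power below
#' 0.01 counts as air).
#'
#' @param geometry A [beamline_geometry()].
#' @param x,y,z Position in mm (scalars).
#' @return One of `"air"`, `"shifter"`, `"brass"`, `"opening"`, `"phantom"`;
#'   for `"phantom"` the voxel's relative stopping power is attached as
#'   attribute `rsp`.
#' @export
classify_point <- function(geometry, x, y, z) {
  if (!all(is.finite(c(x, y, z)))) stop("position must be finite")
  ap <- geometry$aperture
  if (!is.null(ap) && z >= ap$distal_z && z < ap$proximal_z) {
    return(if (point_in_opening(ap, x, y)) "opening" else "brass")
  }
  sh <- geometry$shifter
  if (!is.null(sh) && z >= sh$z0 && z < sh$z1) {
    return(if (x^2 + y^2 <= sh$radius^2) "shifter" else "air")
  }
  ph <- geometry$phantom
  i <- round((c(x, y, z) - ph$origin) / ph$spacing) + 1
  if (all(i >= 1) && all(i <= ph$dims)) {
    rsp <- ph$values[i[1], i[2], i[3]]
    if (rsp >= 0.01) return(structure("phantom", rsp = rsp))
  }
  "air"
}

#' In-air spot sigma of the machine beam model
#'
#' Monotone-decreasing linear interpolation of the in-air spot size at
#' isocenter, anchored at 5.0 mm for 71.3 MeV and 2.0 mm for 228.8 MeV (the
#' machine's lowest and highest energies).
#'
#' @param E Energy in MeV, within the machine span. Vectorized.
#' @return Sigma in mm.
#' @export
in_air_sigma <- function(E) {
  if (any(E < .machine_span[1] | E > .machine_span[2])) {
    stop(sprintf("in_air_sigma: energy outside machine span [%g, %g] MeV",
                 .machine_span[1], .machine_span[2]))
  }
  5 + (E - .machine_span[1]) * (2 - 5) / diff(.machine_span)
}

#' The machine's energy list
#'
#' The 97 deliverable beam energies, spanning 71.3 to 228.8 MeV.
#' @return Numeric vector of length 97.
#' @export
machine_energies <- function() seq(.machine_span[1], .machine_span[2], length.out = 97)

#' Spot list constructor
#'
#' @param energy Energies (MeV) within the machine span.
#' @param x,y Lateral spot positions at the isocenter plane (mm).
#' @param weight Nonnegative spot weights.
#' @param sigma In-air sigma (mm); defaults to the machine beam model.
#' @return Data frame of class `vpmc_spots`.
#' @export
spot_list <- function(energy, x, y, weight = 1, sigma = in_air_sigma(energy)) {
  if (any(weight < 0)) stop("spot weights must be >= 0")
  if (any(energy < .machine_span[1] | energy > .machine_span[2])) {
    stop(sprintf("spot energy outside machine span [%g, %g] MeV",
                 .machine_span[1], .machine_span[2]))
  }
  d <- data.frame(energy = energy, x = x, y = y, weight = weight, sigma = sigma)
  class(d) <- c("vpmc_spots", class(d))
  d
}

#' Water-phantom validation setups
#'
#' Builds the two energy-layer validation configurations: a water tank whose
#' surface lies 108 mm above isocenter, a 30 mm brass aperture on the
#' standard mount (distal face 150 mm from isocenter) with a circular opening
#' of the requested diameter, and a mono-energetic layer of equal-weight
#' spots on a 2.5 mm square grid covering the opening plus a 5 mm outer
#' margin (a circular field). ConfigA: 147.0 MeV, no range shifter.
#' ConfigB: 161.5 MeV with the 45 mm WET shifter (distal face at 190 mm).
#'
#' @param config `"A"` or `"B"`.
#' @param opening_diameter Opening diameter in mm (> 0).
#' @param spacing Phantom/dose voxel spacing in mm.
#' @param lateral_half Phantom lateral half-width in mm.
#' @param depth Phantom depth in mm.
#' @return List with elements `geometry` (a `vpmc_beamline`) and `spots`.
#' @export
build_config <- function(config = c("A", "B"), opening_diameter,
                         spacing = 1, lateral_half = 45, depth = 180) {
  config <- match.arg(config)
  if (opening_diameter <= 0) stop("opening diameter must be > 0")
  r_open <- opening_diameter / 2
  energy <- if (config == "A") 147.0 else 161.5
  ap <- aperture_block(circle_polygon(r_open))
  phantom <- water_box(lateral_half = lateral_half, depth = depth,
                       spacing = spacing)
  geom <- beamline_geometry(machine = if (config == "A") "AP" else "APRS",
                            aperture = ap, phantom = phantom)
  g <- seq(-ceiling((r_open + 5) / 2.5), ceiling((r_open + 5) / 2.5)) * 2.5
  sp <- expand.grid(x = g, y = g)
  sp <- sp[sqrt(sp$x^2 + sp$y^2) <= r_open + 5, ]
  spots <- spot_list(energy = rep(energy, nrow(sp)), x = sp$x, y = sp$y)
  list(geometry = geom, spots = spots)
}

# ---- phantom fixtures -----------------------------------------------------

#' Synthetic phantoms
#'
#' Deterministic phantom builders used throughout the validation suite.
#' `water_box()` is a uniform RSP-1 tank with its surface `surface_z` mm
#' above isocenter. `slab_insert_phantom()` inserts a bone-like slab
#' (RSP 1.6) and an air slab (RSP 0.001) at the given depths.
#' `toy_head_phantom()` is a water ellipsoid with a 4 mm bone shell in air,
#' a synthetic stand-in for patient heterogeneity.
#'
#' @param lateral_half Lateral half-width in mm.
#' @param depth Tank depth in mm.
#' @param spacing Voxel spacing in mm (isotropic).
#' @param surface_z z of the water surface (mm above isocenter).
#' @return A `vpmc_grid` of relative stopping powers.
#' @export
water_box <- function(lateral_half = 45, depth = 180, spacing = 1,
                      surface_z = 108) {
  nl <- 2 * floor(lateral_half / spacing) + 1
  nz <- round(depth / spacing)
  vals <- array(1, dim = c(nl, nl, nz))
  origin <- c(-(nl - 1) / 2 * spacing, -(nl - 1) / 2 * spacing,
              surface_z - spacing / 2 - (nz - 1) * spacing)
  vpmc_grid(vals, origin, rep(spacing, 3))
}

#' @rdname water_box
#' @param bone_depth,air_depth Depth span (mm below the surface) of the bone
#'   and air slabs, each as `c(from, to)`.
#' @export
slab_insert_phantom <- function(lateral_half = 45, depth = 180, spacing = 1,
                                surface_z = 108, bone_depth = c(40, 50),
                                air_depth = c(60, 65)) {
  g <- water_box(lateral_half, depth, spacing, surface_z)
  d <- surface_z - grid_axis(g, 3)  # depth below surface of voxel centers
  g$values[, , d > bone_depth[1] & d <= bone_depth[2]] <- 1.6
  g$values[, , d > air_depth[1] & d <= air_depth[2]] <- 0.001
  g
}

#' @rdname water_box
#' @param semi_axes Ellipsoid semi-axes (mm).
#' @param shell Bone-shell thickness (mm).
#' @export
toy_head_phantom <- function(lateral_half = 50, depth = 140, spacing = 2,
                             surface_z = 70, semi_axes = c(40, 45, 60),
                             shell = 4) {
  nl <- 2 * floor(lateral_half / spacing) + 1
  nz <- round(depth / spacing)
  origin <- c(-(nl - 1) / 2 * spacing, -(nl - 1) / 2 * spacing,
              surface_z - spacing / 2 - (nz - 1) * spacing)
  xs <- origin[1] + (seq_len(nl) - 1) * spacing
  zs <- origin[3] + (seq_len(nz) - 1) * spacing
  cz <- surface_z - semi_axes[3]  # ellipsoid center on the beam axis
  r2 <- outer(outer((xs / semi_axes[1])^2, (xs / semi_axes[2])^2, "+"),
              ((zs - cz) / semi_axes[3])^2, "+")
  r2in <- outer(outer((xs / (semi_axes[1] - shell))^2,
                      (xs / (semi_axes[2] - shell))^2, "+"),
                ((zs - cz) / (semi_axes[3] - shell))^2, "+")
  vals <- array(0.001, dim = c(nl, nl, nz))
  vals[r2 <= 1] <- 1.6
  vals[r2in <= 1] <- 1.0
  vpmc_grid(vals, origin, rep(spacing, 3))
}

#' Spherical mask on a grid
#'
#' @param grid A `vpmc_grid`.
#' @param center Sphere center (mm).
#' @param radius Sphere radius (mm).
#' @return Logical 3D array over the grid's voxels.
#' @export
sphere_mask <- function(grid, center, radius) {
  xs <- grid_axis(grid, 1); ys <- grid_axis(grid, 2); zs <- grid_axis(grid, 3)
  r2 <- outer(outer((xs - center[1])^2, (ys - center[2])^2, "+"),
              (zs - center[3])^2, "+")
  r2 <= radius^2
}

#' Aperture opening polygon from a target mask
#'
#' Reproduces the clinical margin recipe: the target (CTV) mask is dilated
#' isotropically by `ptv_margin` to form the PTV, projected along the beam
#' axis into the beam's-eye view, dilated laterally by `block_margin`, and
#' the silhouette boundary is returned as a simple polygon (convex hull of
#' the dilated pixel corners, which is guaranteed to contain every dilated
#' target pixel).
#'
#' @param mask Logical 3D array (target voxels) on `grid`.
#' @param grid The `vpmc_grid` carrying the mask.
#' @param ptv_margin Isotropic 3D margin in mm (default 1).
#' @param block_margin Additional 2D margin in mm (default 2).
#' @return n x 2 polygon matrix in mm.
#' @export
opening_from_target <- function(mask, grid, ptv_margin = 1, block_margin = 2) {
  if (!any(mask)) stop("empty target mask")
  sp <- grid$spacing
  idx <- which(mask, arr.ind = TRUE)
  pos <- cbind(grid$origin[1] + (idx[, 1] - 1) * sp[1],
               grid$origin[2] + (idx[, 2] - 1) * sp[2],
               grid$origin[3] + (idx[, 3] - 1) * sp[3])
  # 3D dilation by ptv_margin followed by BEV projection and 2D dilation by
  # block_margin: every projected voxel center carries a lateral disc of
  # radius (ptv + block margin)
  r <- ptv_margin + block_margin
  pts <- unique(pos[, 1:2, drop = FALSE])
  th <- 2 * pi * (0:15) / 16
  ring <- cbind(r * cos(th), r * sin(th))
  # corners of each projected voxel footprint so the silhouette area (not
  # just its centers) is covered, pushed out by the margin disc
  half <- cbind(c(-1, -1, 1, 1) * sp[1] / 2, c(-1, 1, -1, 1) * sp[2] / 2)
  corners <- do.call(rbind, lapply(seq_len(4), function(k) {
    cbind(pts[, 1] + half[k, 1], pts[, 2] + half[k, 2])
  }))
  cloud <- do.call(rbind, lapply(seq_len(nrow(ring)), function(j) {
    cbind(corners[, 1] + ring[j, 1], corners[, 2] + ring[j, 2])
  }))
  hull <- grDevices::chull(cloud[, 1], cloud[, 2])
  cloud[rev(hull), , drop = FALSE]  # counter-clockwise simple polygon
}
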