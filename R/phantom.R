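# Synthetic phantoms ------------------------------------------------------
#
# A phantom is described by three pixel maps on the object grid:
#   transmission I_R in (0, 1]     (attenuation channel)
#   refraction   dphi_R in rad     (x-gradient of the optical path, DPC)
#   scatter_var  sigma^2 in rad^2  (variance of the stochastic scattering
#                                   angle, dark-field channel)
# Maps are built by projecting simple solids (slabs, cylinders, spheres,
# wedges) of materials with complex refractive index n = 1 - delta + i*beta
# at a single design energy.  Projected thicknesses are additive, so
# overlapping shapes composite by summation of delta*t, beta*t and s*t.

#' Define a phantom material
#'
#' @param delta refractive index decrement (dimensionless), phase term of
#'   `n = 1 - delta + i beta`.
#' @param beta absorption index (dimensionless).
#' @param scatter dark-field strength: variance of the stochastic
#'   scattering angle accrued per unit projected thickness (rad^2/um).
#' @param name optional label.
#' @return list of class `ei_material`.
#' @examples
#' ei_material(1.06e-7, 2.2e-10, name = "PMMA @ 50 keV")
#' @export
ei_material <- function(delta, beta, scatter = 0, name = NULL) {
  if (!is.numeric(delta) || !is.numeric(beta) || !is.numeric(scatter) ||
      delta < 0 || beta < 0 || scatter < 0)
    stop("material parameters delta, beta, scatter must be non-negative")
  structure(list(delta = delta, beta = beta, scatter = scatter,
                 name = if (is.null(name)) "material" else name),
            class = "ei_material")
}

# shape constructors: each carries a projected-thickness profile t(x, y)
# in micrometres.  x is the scan (phase-sensitive) direction.

#' Phantom shapes
#'
#' Constructors for the solids understood by [generate_phantom()]. All
#' coordinates and sizes are micrometres in the object plane; `x` is the
#' scan direction, `y` vertical. Each shape has a projected thickness
#' profile along the beam:
#' * `shape_slab()`: constant thickness over `x0 <= x <= x1`.
#' * `shape_cylinder()`: circular cylinder with axis along y,
#'   `t(x) = 2 sqrt(r^2 - (x - x0)^2)`.
#' * `shape_sphere()`: `t(x, y) = 2 sqrt(r^2 - rho^2)`.
#' * `shape_wedge()`: thickness rising linearly from 0 at `x0` to
#'   `thickness` at `x1`.
#'
#' @param x0,x1,y0,y1 extents (um); `y0`/`y1` default to the full grid.
#' @param radius radius (um).
#' @param thickness slab thickness / wedge maximum thickness (um).
#' @param material an [ei_material()].
#' @return list of class `ei_shape`.
#' @name ei_shapes
NULL

new_shape <- function(type, material, fields) {
  stopifnot(inherits(material, "ei_material"))
  structure(c(list(type = type, material = material), fields),
            class = "ei_shape")
}

#' @rdname ei_shapes
#' @export
shape_slab <- function(x0, x1, thickness, material, y0 = -Inf, y1 = Inf) {
  if (x1 <= x0 || thickness <= 0) stop("slab needs x1 > x0, thickness > 0")
  new_shape("slab", material,
            list(x0 = x0, x1 = x1, thickness = thickness, y0 = y0, y1 = y1))
}

#' @rdname ei_shapes
#' @export
shape_cylinder <- function(x0, radius, material, y0 = -Inf, y1 = Inf) {
  if (radius <= 0) stop("cylinder needs radius > 0")
  new_shape("cylinder", material,
            list(x0 = x0, radius = radius, y0 = y0, y1 = y1))
}

#' @rdname ei_shapes
#' @export
shape_sphere <- function(x0, y0, radius, material) {
  if (radius <= 0) stop("sphere needs radius > 0")
  new_shape("sphere", material, list(x0 = x0, y0 = y0, radius = radius))
}

#' @rdname ei_shapes
#' @export
shape_wedge <- function(x0, x1, thickness, material, y0 = -Inf, y1 = Inf) {
  if (x1 <= x0 || thickness <= 0) stop("wedge needs x1 > x0, thickness > 0")
  new_shape("wedge", material,
            list(x0 = x0, x1 = x1, thickness = thickness, y0 = y0, y1 = y1))
}

# thickness profile of one shape on the (ny x nx) grid, in um
shape_thickness <- function(shape, X, Y) {
  t <- switch(shape$type,
    slab = ifelse(X >= shape$x0 & X <= shape$x1, shape$thickness, 0),
    wedge = ifelse(X >= shape$x0 & X <= shape$x1,
                   shape$thickness * (X - shape$x0) / (shape$x1 - shape$x0),
                   0),
    cylinder = {
      d2 <- shape$radius^2 - (X - shape$x0)^2
      ifelse(d2 > 0, 2 * sqrt(pmax(d2, 0)), 0)
    },
    sphere = {
      d2 <- shape$radius^2 - (X - shape$x0)^2 - (Y - shape$y0)^2
      ifelse(d2 > 0, 2 * sqrt(pmax(d2, 0)), 0)
    },
    stop("unknown shape type: ", shape$type))
  if (!is.null(shape$y0) && shape$type != "sphere")
    t[Y < shape$y0 | Y > shape$y1] <- 0
  t
}

# x-ray wavenumber at E keV, in 1/um (lambda_um = 1.23984193e-3 / E_keV)
xray_wavenumber <- function(energy_kev) {
  if (energy_kev <= 0) stop("energy must be positive (keV)")
  2 * pi / (1.23984193e-3 / energy_kev)
}

#' Generate phantom maps from a shape list
#'
#' Projects a list of solids onto the object pixel grid and derives the
#' three retrievable channels: `transmission = exp(-2 k sum(beta_i t_i))`,
#' `refraction = d/dx sum(delta_i t_i)` (central finite differences along
#' the scan direction, one-sided at the grid edges) and
#' `scatter_var = sum(s_i t_i)`.
#'
#' The grid is centred on x = y = 0 with pixels sampled at their centres;
#' pixel (1, 1) is the bottom-left (most negative x and y) corner, rows
#' index y and columns index x.
#'
#' @param shapes list of [ei_shapes] (may be empty for a vacuum phantom).
#' @param nx,ny grid size along the scan (x) and vertical (y) directions.
#' @param pixel_size object pixel size (um); in the scanning acquisition
#'   this equals the scan step.
#' @param energy_kev design x-ray energy (keV).
#' @param transmission_floor transmission values that underflow below this
#'   floor are clipped to it, with a warning.
#' @return An object of class `phantom_maps`: list with matrices
#'   `transmission`, `refraction` (rad), `scatter_var` (rad^2), and fields
#'   `pixel_size`, `energy_kev`, `shape` (= `c(ny, nx)`).
#' @examples
#' ph <- generate_phantom(list(), nx = 8, ny = 2, pixel_size = 75,
#'                        energy_kev = 50)
#' all(ph$transmission == 1)
#' @export
generate_phantom <- function(shapes, nx, ny, pixel_size, energy_kev = 50,
                             transmission_floor = 1e-12) {
  if (!is.list(shapes)) stop("`shapes` must be a list of ei_shape objects")
  if (length(shapes) && !all(vapply(shapes, inherits, TRUE, "ei_shape")))
    stop("every element of `shapes` must be an ei_shape")
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 2L || ny < 1L) stop("grid must have nx >= 2 and ny >= 1")
  if (pixel_size <= 0) stop("`pixel_size` must be positive")
  x <- (seq_len(nx) - (nx + 1) / 2) * pixel_size
  y <- (seq_len(ny) - (ny + 1) / 2) * pixel_size
  X <- matrix(x, ny, nx, byrow = TRUE)
  Y <- matrix(y, ny, nx)
  bt <- dt <- st <- matrix(0, ny, nx)   # beta*t, delta*t, s*t
  for (sh in shapes) {
    t <- shape_thickness(sh, X, Y)
    bt <- bt + sh$material$beta * t
    dt <- dt + sh$material$delta * t
    st <- st + sh$material$scatter * t
  }
  k <- xray_wavenumber(energy_kev)
  transmission <- exp(-2 * k * bt)
  n_under <- sum(transmission < transmission_floor)
  if (n_under > 0) {
    warning(sprintf(
      "transmission underflow in %d pixel(s); clipped to floor %g",
      n_under, transmission_floor))
    transmission <- pmax(transmission, transmission_floor)
  }
  refraction <- gradient_x(dt, pixel_size)
  structure(list(transmission = transmission, refraction = refraction,
                 scatter_var = st, pixel_size = pixel_size,
                 energy_kev = energy_kev, shape = c(ny, nx)),
            class = "phantom_maps")
}

# central differences along columns (x), one-sided at the two edges
gradient_x <- function(m, dx) {
  nx <- ncol(m)
  g <- matrix(0, nrow(m), nx)
  if (nx >= 3L)
    g[, 2:(nx - 1L)] <- (m[, 3:nx, drop = FALSE] -
                           m[, 1:(nx - 2L), drop = FALSE]) / (2 * dx)
  g[, 1L] <- (m[, 2L] - m[, 1L]) / dx
  g[, nx] <- (m[, nx] - m[, nx - 1L]) / dx
  g
}

#' @export
print.phantom_maps <- function(x, ...) {
  cat(sprintf(
    "<phantom_maps> %d x %d pixels (%g um), %g keV; transmission [%.3g, %.3g], |refraction| <= %.3g rad, scatter_var <= %.3g rad^2\n",
    x$shape[1], x$shape[2], x$pixel_size, x$energy_kev,
    min(x$transmission), max(x$transmission),
    max(abs(x$refraction)), max(x$scatter_var)))
  invisible(x)
}

# A few illustrative materials at ~50 keV (tabulated delta/beta rounded to
# two figures; scatter strengths are invented plausible values since DF is
# a sub-pixel microstructure property, not a bulk constant).
#' Example materials
#'
#' Approximate optical constants at 50 keV for use in examples and the
#' demo phantom. `scatter` values are synthetic: dark-field strength
#' depends on microstructure, not on composition alone.
#' @return an [ei_material()].
#' @name ei_materials
NULL

#' @rdname ei_materials
#' @export
material_pmma <- function() ei_material(1.06e-7, 2.2e-10, 0, "PMMA")

#' @rdname ei_materials
#' @export
material_aluminium <- function() ei_material(2.1e-7, 1.5e-9, 0, "aluminium")

#' @rdname ei_materials
#' @export
material_foam <- function()
  ei_material(3e-8, 8e-11, 4e-15, "scattering foam (synthetic)")
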