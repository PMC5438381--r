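# Run configuration --------------------------------------------------------
#
# A single JSON file drives the whole pipeline.  Parsing is strict: unknown
# keys are rejected, and the md5 of the canonical (minified) serialization
# is attached as the provenance hash carried by every output.

config_schema <- list(
  geometry = c("z_m1", "z_m2", "z_det", "detector_pitch", "focal_spot",
               "z_sample"),
  masks = list(m1 = c("pitch", "aperture", "shifts"),
               m2 = c("pitch", "aperture")),
  ic = c("peak", "width", "baseline", "center", "shape", "global_offset",
         "inner_fraction"),
  phantom = c("nx", "ny", "pixel_size", "energy_kev", "shapes"),
  acquisition = c("flux", "frame_rate", "speed", "n_columns", "n_flats",
                  "seed", "noise"),
  retrieval = c("mode", "interpolate", "delta_beta", "clip_floor")
)
shape_keys <- c("type", "x0", "x1", "y0", "y1", "radius", "thickness",
                "material")
material_keys <- c("delta", "beta", "scatter", "name")

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop(sprintf("unknown configuration key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")))
}

#' Default run configuration
#'
#' The stated laboratory system: masks at 1.5/1.95 m with 75/97.5 um
#' pitches and 21.4/28 um apertures, detector at 2 m with 100 um pixels,
#' asymmetric subgroup shifts `{-s, 0, s, 2s}` with `s = 10` um aligned by
#' a global offset of `-s/2` so the four IC points sit at
#' `{-15, -5, +5, +15}` um, and an IC width chosen so the outer pair falls
#' at 50% of the maximum (`15 / sqrt(2 log 2)` um). The IC peak is 0.9
#' with a 0.01 pedestal (thick gold septa transmit little at these
#' energies). Acquisition: 32 Hz, 2.5 mm/s, 128 columns, flux 1e4.
#'
#' @return A nested list of class `run_config` with a `hash` attribute.
#' @export
default_config <- function() {
  cfg <- list(
    geometry = list(z_m1 = 1.5, z_m2 = 1.95, z_det = 2.0,
                    detector_pitch = 100, focal_spot = 80, z_sample = 1.5),
    masks = list(m1 = list(pitch = 75, aperture = 21.4,
                           shifts = c(-10, 0, 10, 20)),
                 m2 = list(pitch = 97.5, aperture = 28)),
    ic = list(peak = 0.9, width = 15 / sqrt(2 * log(2)), baseline = 0.01,
              center = 0, shape = "gaussian", global_offset = -5,
              inner_fraction = 1 / 3),
    phantom = list(nx = 192, ny = 24, pixel_size = 75, energy_kev = 50,
                   shapes = list()),
    acquisition = list(flux = 1e4, frame_rate = 32, speed = 2.4,
                       n_columns = 128, n_flats = 100, seed = 1,
                       noise = TRUE),
    retrieval = list(mode = "multimodal", interpolate = FALSE,
                     delta_beta = 482, clip_floor = 0))
  as_run_config(cfg)
}

as_run_config <- function(cfg) {
  check_keys(cfg, names(config_schema), "top level")
  for (block in c("geometry", "ic", "phantom", "acquisition", "retrieval"))
    if (!is.null(cfg[[block]]))
      check_keys(cfg[[block]], config_schema[[block]], block)
  if (!is.null(cfg$masks)) {
    check_keys(cfg$masks, c("m1", "m2"), "masks")
    if (!is.null(cfg$masks$m1))
      check_keys(cfg$masks$m1, config_schema$masks$m1, "masks.m1")
    if (!is.null(cfg$masks$m2))
      check_keys(cfg$masks$m2, config_schema$masks$m2, "masks.m2")
  }
  for (sh in cfg$phantom$shapes) {
    check_keys(sh, shape_keys, "phantom.shapes[]")
    if (!is.null(sh$material))
      check_keys(sh$material, material_keys, "phantom.shapes[].material")
  }
  structure(cfg, class = "run_config", hash = config_hash(cfg))
}

#' Read a run configuration from JSON
#'
#' Strict parser: unknown keys anywhere in the file are rejected; the md5
#' hash of the canonical serialization is attached (attribute `"hash"`)
#' and propagated into every output the pipeline writes.
#'
#' @param path path to a JSON configuration file (see [default_config()]
#'   for the block layout, and [write_run_config()] to produce a template).
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Configuration hash
#'
#' md5 of the canonical minified JSON serialization; identical
#' configurations hash identically regardless of file formatting.
#'
#' @param cfg a `run_config` or plain nested list.
#' @return hex string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = I(17))
  unname(tools::md5sum(tmp))
}

# -- constructors from a config -------------------------------------------

config_geometry <- function(cfg) {
  g <- cfg$geometry
  system_geometry(g$z_m1, g$z_m2, g$z_det, g$detector_pitch, g$focal_spot,
                  if (is.null(g$z_sample)) g$z_m1 else g$z_sample)
}

config_ic <- function(cfg) {
  ic <- cfg$ic
  make_ic(ic$peak, ic$width, ic$baseline, ic$center,
          if (is.null(ic$shape)) "gaussian" else ic$shape)
}

config_scheme <- function(cfg) {
  ic <- config_ic(cfg)
  shifts <- cfg$masks$m1$shifts
  if (is.null(shifts))
    place_half_max_scheme(ic, cfg$ic$inner_fraction)
  else
    scheme_from_shifts(ic, as.numeric(shifts), cfg$ic$global_offset)
}

config_shape <- function(sh) {
  m <- sh$material
  mat <- ei_material(m$delta, m$beta,
                     if (is.null(m$scatter)) 0 else m$scatter, m$name)
  inf_or <- function(v, d) if (is.null(v)) d else v
  switch(sh$type,
    slab = shape_slab(sh$x0, sh$x1, sh$thickness, mat,
                      inf_or(sh$y0, -Inf), inf_or(sh$y1, Inf)),
    wedge = shape_wedge(sh$x0, sh$x1, sh$thickness, mat,
                        inf_or(sh$y0, -Inf), inf_or(sh$y1, Inf)),
    cylinder = shape_cylinder(sh$x0, sh$radius, mat,
                              inf_or(sh$y0, -Inf), inf_or(sh$y1, Inf)),
    sphere = shape_sphere(sh$x0, sh$y0, sh$radius, mat),
    stop("unknown phantom shape type: ", sh$type))
}

config_phantom <- function(cfg) {
  p <- cfg$phantom
  shapes <- lapply(p$shapes, config_shape)
  generate_phantom(shapes, p$nx, p$ny, p$pixel_size, p$energy_kev)
}
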