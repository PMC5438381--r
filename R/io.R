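# Plain-text I/O for frame stacks and retrieved channels ------------------
#
# Outputs are written as portable text bundles: TSV matrices (data.table)
# plus a JSON metadata / provenance sidecar.  This keeps every artefact
# human-inspectable and diff-able; TIFF/HDF5 writers can be slotted behind
# the same functions where those libraries are available.

write_matrix_tsv <- function(m, path) {
  data.table::fwrite(data.table::as.data.table(m), path, sep = "\t",
                     col.names = FALSE)
}

read_matrix_tsv <- function(path) {
  as.matrix(data.table::fread(path, sep = "\t", header = FALSE))
}

# 3-D array (f x ny x C) <-> (f*ny) x C table, dims in metadata
flatten_stack <- function(a) {
  d <- dim(a)
  matrix(aperm(a, c(2L, 1L, 3L)), d[1L] * d[2L], d[3L])
}

unflatten_stack <- function(m, d) {
  aperm(array(m, dim = c(d[2L], d[1L], d[3L])), c(2L, 1L, 3L))
}

#' Write / read a frame bundle
#'
#' A frame bundle is a directory holding `counts.tsv`, `flats_before.tsv`,
#' `flats_after.tsv` (frame-major flattened stacks) and `meta.json` with
#' the array dimensions, column subgroup table, scan step, flux, seed,
#' sampling-scheme parameters and configuration hash.
#'
#' @param frames a [scan_frames][simulate_scan] object.
#' @param dir output directory (created if missing).
#' @param config_hash optional provenance hash stored in the metadata.
#' @return `dir`, invisibly (`write_frames`); a `scan_frames` object
#'   (`read_frames`).
#' @export
write_frames <- function(frames, dir, config_hash = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(flatten_stack(frames$counts), file.path(dir, "counts.tsv"))
  write_matrix_tsv(flatten_stack(frames$flats_before),
                   file.path(dir, "flats_before.tsv"))
  write_matrix_tsv(flatten_stack(frames$flats_after),
                   file.path(dir, "flats_after.tsv"))
  ic <- frames$scheme$ic
  meta <- list(
    dim_counts = dim(frames$counts),
    dim_flats = dim(frames$flats_before),
    column_subgroup = frames$column_subgroup,
    scan_step = frames$scan_step,
    flux_per_frame = frames$flux_per_frame,
    seed = frames$seed,
    spacing_steps = frames$spacing_steps,
    nx = frames$nx,
    noise = frames$noise,
    disp_per_rad = frames$disp_per_rad,
    ic = list(peak_amplitude = ic$peak_amplitude, width = ic$width,
              baseline = ic$baseline, center = ic$center, shape = ic$shape),
    scheme_positions = frames$scheme$positions,
    config_hash = config_hash)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(dir)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  ic <- make_ic(meta$ic$peak_amplitude, meta$ic$width, meta$ic$baseline,
                meta$ic$center, meta$ic$shape)
  scheme <- new_sampling_scheme(ic, meta$scheme_positions)
  structure(
    list(counts = unflatten_stack(
           read_matrix_tsv(file.path(dir, "counts.tsv")), meta$dim_counts),
         flats_before = unflatten_stack(
           read_matrix_tsv(file.path(dir, "flats_before.tsv")),
           meta$dim_flats),
         flats_after = unflatten_stack(
           read_matrix_tsv(file.path(dir, "flats_after.tsv")),
           meta$dim_flats),
         column_subgroup = as.integer(meta$column_subgroup),
         scan_step = meta$scan_step, flux_per_frame = meta$flux_per_frame,
         seed = as.integer(meta$seed), scheme = scheme,
         disp_per_rad = meta$disp_per_rad,
         spacing_steps = meta$spacing_steps, nx = meta$nx,
         noise = isTRUE(meta$noise)),
    class = "scan_frames")
}

#' Write retrieved channels with provenance
#'
#' One TSV per channel (`absorption.tsv`, `dpc.tsv`, `darkfield.tsv`, or
#' `phase_map.tsv` in single-shot mode) plus `provenance.json` carrying the
#' sampling-scheme point values, number of summed images, seed and config
#' hash.
#'
#' @param ret a `retrieved_images` object.
#' @param dir output directory.
#' @param n_summed,seed,config_hash provenance fields.
#' @return `dir`, invisibly.
#' @export
write_retrieved <- function(ret, dir, n_summed = NULL, seed = NULL,
                            config_hash = NULL) {
  stopifnot(inherits(ret, "retrieved_images"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(ret$phase_map)) {
    write_matrix_tsv(ret$phase_map, file.path(dir, "phase_map.tsv"))
    channels <- "phase_map"
  } else {
    write_matrix_tsv(ret$absorption, file.path(dir, "absorption.tsv"))
    write_matrix_tsv(ret$dpc, file.path(dir, "dpc.tsv"))
    write_matrix_tsv(ret$darkfield, file.path(dir, "darkfield.tsv"))
    channels <- c("absorption", "dpc", "darkfield")
  }
  sch <- ret$scheme
  prov <- list(channels = channels,
               scheme_offsets = sch$offsets, R = sch$R, Rd = sch$Rd,
               Rdd = sch$Rdd, n_summed = n_summed, n_bad = ret$n_bad,
               seed = seed, config_hash = config_hash,
               units = list(dpc = "um (M1 displacement)",
                            darkfield = "um^2 (M1 displacement)",
                            phase_map = "rad"))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(dir)
}

#' Write phantom maps to a text bundle
#'
#' @param phantom a [phantom_maps][generate_phantom] object.
#' @param dir output directory.
#' @param config_hash optional provenance hash.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir, config_hash = NULL) {
  stopifnot(inherits(phantom, "phantom_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(phantom$transmission, file.path(dir, "transmission.tsv"))
  write_matrix_tsv(phantom$refraction, file.path(dir, "refraction.tsv"))
  write_matrix_tsv(phantom$scatter_var, file.path(dir, "scatter_var.tsv"))
  jsonlite::write_json(
    list(shape = phantom$shape, pixel_size = phantom$pixel_size,
         energy_kev = phantom$energy_kev, config_hash = config_hash),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = I(17),
    pretty = TRUE)
  invisible(dir)
}
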