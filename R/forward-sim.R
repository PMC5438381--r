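# Forward simulation of the asymmetric-EI object scan ---------------------
#
# The acquisition model: detector columns are grouped in repeating blocks
# of four; the aperture subgroup feeding column c samples the IC at point
# j(c).  The object is translated along x; at frame f, column c sees the
# object column  o = f - (c - 1) * spacing  (vacuum outside the phantom).
# Expected normalized intensity follows the second-order Taylor expansion
# of the IC, and counts are Poisson draws around flux * intensity.

#' Expected normalized intensity at one IC sampling point
#'
#' Second-order Taylor forward model of the IC response:
#' `I_j = I_R * (R_j + Rd_j * dphi + 0.5 * Rdd_j * (dphi^2 + s2))`,
#' with the object refraction `dphi` and scattering variance `s2` already
#' expressed in IC-displacement units (um and um^2 at the M1 plane; see
#' [displacement_per_radian()]).
#'
#' @param scheme a `sampling_scheme`.
#' @param j IC point index in 1..4.
#' @param I_R object transmission (0, 1], vectorized.
#' @param dphi refraction expressed as IC displacement (um), vectorized.
#' @param s2 scattering variance in displacement units (um^2), vectorized.
#' @param clip if `TRUE` (default) negative intensities, which can occur
#'   when the expansion is driven far outside its validity, are clipped to
#'   zero; the number of clipped values is attached as attribute
#'   `"n_clipped"`.
#' @return numeric vector/matrix of expected normalized intensities.
#' @examples
#' sch <- place_half_max_scheme(make_ic(1, 10))
#' expected_intensity(sch, 1, 1, 0, 0)  # equals sch$R[1]
#' @export
expected_intensity <- function(scheme, j, I_R, dphi = 0, s2 = 0,
                               clip = TRUE) {
  stopifnot(inherits(scheme, "sampling_scheme"))
  j <- as.integer(j)
  if (any(j < 1L | j > 4L)) stop("`j` must index one of the 4 IC points")
  if (any(s2 < 0)) stop("scattering variance `s2` must be >= 0")
  I <- I_R * (scheme$R[j] + scheme$Rd[j] * dphi +
                0.5 * scheme$Rdd[j] * (dphi^2 + s2))
  n_neg <- sum(I < 0)
  if (clip && n_neg > 0) I[I < 0] <- 0
  attr(I, "n_clipped") <- if (clip) n_neg else 0L
  I
}

# deterministic per-frame substream so that reordering columns or frames in
# the implementation cannot change the draws attributed to a frame
frame_seed <- function(seed, stream, f) {
  (as.integer(seed) + 1000003L * as.integer(stream) +
     2971L * as.integer(f)) %% 2147483629L
}

# expected intensity map for one frame: ny x n_columns matrix
frame_expectation <- function(f, phantom_disp, subgroup, scheme, spacing,
                              ny, n_columns) {
  o <- f - (seq_len(n_columns) - 1L) * spacing
  valid <- o >= 1L & o <= phantom_disp$nx
  IR <- matrix(1, ny, n_columns)
  D <- S <- matrix(0, ny, n_columns)
  if (any(valid)) {
    IR[, valid] <- phantom_disp$transmission[, o[valid], drop = FALSE]
    D[, valid] <- phantom_disp$dphi[, o[valid], drop = FALSE]
    S[, valid] <- phantom_disp$s2[, o[valid], drop = FALSE]
  }
  Rj <- scheme$R[subgroup]
  Rdj <- scheme$Rd[subgroup]
  Rddj <- scheme$Rdd[subgroup]
  E <- IR * (matrix(Rj, ny, n_columns, byrow = TRUE) +
               matrix(Rdj, ny, n_columns, byrow = TRUE) * D +
               0.5 * matrix(Rddj, ny, n_columns, byrow = TRUE) * (D^2 + S))
  E[E < 0] <- 0
  E
}

#' Simulate the asymmetric-EI object scan
#'
#' Produces the per-frame, per-column photon counts of a lateral object
#' scan through the two-mask system, plus flat stacks recorded without the
#' sample before and after the scan. Each beamlet samples the phantom at a
#' single x position (delta-aperture model); refraction angles and
#' scattering variances are converted to IC-displacement units with the
#' geometry lever arm. Counts are Poisson distributed with expectation
#' `flux_per_frame * I_j`; with `noise = FALSE` the exact expectations are
#' returned (as doubles), which is the reference for algorithm-only tests.
#'
#' @param phantom a [phantom_maps][generate_phantom] object.
#' @param geom a [system_geometry()].
#' @param scheme a `sampling_scheme` (see [scheme_from_shifts()]).
#' @param flux_per_frame expected photons per column per frame on the IC
#'   maximum scale (i.e. a column at an IC point with `R_j = 1` and no
#'   sample collects on average `flux_per_frame` counts).
#' @param n_columns number of detector columns; must be a multiple of 4.
#'   The prototype used 128 (32 columns per asymmetric subgroup).
#' @param n_flats number of flat frames in each of the before/after stacks.
#' @param seed integer RNG seed; all draws derive deterministic per-frame
#'   substreams from it.
#' @param spacing_steps column-to-column spacing of the beamlets on the
#'   object, in scan steps (integer; 1 when the scan step equals the
#'   demagnified detector pitch, as in the prototype).
#' @param noise draw Poisson counts (`TRUE`) or return expectations scaled
#'   by the flux (`FALSE`).
#' @return An object of class `scan_frames`: list with `counts`
#'   (`n_frames x ny x n_columns` array), `flats_before` / `flats_after`
#'   (`n_flats x ny x n_columns`), `column_subgroup`, `scan_step` (um),
#'   `flux_per_frame`, `seed`, `scheme`, `disp_per_rad`, `spacing_steps`,
#'   `nx`, `noise`.
#' @export
simulate_scan <- function(phantom, geom, scheme, flux_per_frame,
                          n_columns = 128L, n_flats = 100L, seed = 1L,
                          spacing_steps = 1L, noise = TRUE) {
  stopifnot(inherits(phantom, "phantom_maps"),
            inherits(geom, "system_geometry"),
            inherits(scheme, "sampling_scheme"))
  if (!is.numeric(flux_per_frame) || flux_per_frame <= 0)
    stop("`flux_per_frame` must be positive")
  n_columns <- as.integer(n_columns)
  if (n_columns < 4L || n_columns %% 4L != 0L)
    stop("`n_columns` must be a positive multiple of 4 so that every ",
         "subgroup has the same number of columns")
  spacing_steps <- as.integer(spacing_steps)
  if (spacing_steps < 1L) stop("`spacing_steps` must be a positive integer")
  ny <- phantom$shape[1]; nx <- phantom$shape[2]
  g <- displacement_per_radian(geom)
  phantom_disp <- list(transmission = phantom$transmission,
                       dphi = phantom$refraction * g,
                       s2 = phantom$scatter_var * g^2,
                       nx = nx)
  subgroup <- ((seq_len(n_columns) - 1L) %% 4L) + 1L
  n_frames <- nx + (n_columns - 1L) * spacing_steps
  counts <- array(0, dim = c(n_frames, ny, n_columns))
  for (f in seq_len(n_frames)) {
    E <- flux_per_frame * frame_expectation(f, phantom_disp, subgroup,
                                            scheme, spacing_steps, ny,
                                            n_columns)
    counts[f, , ] <- if (noise) {
      set.seed(frame_seed(seed, 1L, f))
      stats::rpois(length(E), E)
    } else E
  }
  flats <- simulate_flats(scheme, n_columns, ny, flux_per_frame,
                          n_flats = n_flats, seed = seed, noise = noise)
  structure(
    list(counts = counts, flats_before = flats$before,
         flats_after = flats$after, column_subgroup = subgroup,
         scan_step = phantom$pixel_size, flux_per_frame = flux_per_frame,
         seed = as.integer(seed), scheme = scheme, disp_per_rad = g,
         spacing_steps = spacing_steps, nx = nx, noise = noise),
    class = "scan_frames")
}

#' Simulate flat (no-sample) frame stacks
#'
#' Flats are object-free acquisitions: every column's expected count is
#' `flux * R_j` for its subgroup's IC point. Two stacks are returned,
#' emulating the references recorded before and after each sample scan; no
#' drift between them is modelled.
#'
#' @param scheme a `sampling_scheme`.
#' @param n_columns,ny detector layout (columns / rows).
#' @param flux expected photons per column per frame at `R = 1`.
#' @param n_flats frames per stack.
#' @param seed integer RNG seed.
#' @param noise Poisson draws (`TRUE`) or exact expectations.
#' @return list with arrays `before` and `after`, each
#'   `n_flats x ny x n_columns`.
#' @export
simulate_flats <- function(scheme, n_columns = 128L, ny = 1L, flux,
                           n_flats = 100L, seed = 1L, noise = TRUE) {
  stopifnot(inherits(scheme, "sampling_scheme"))
  if (flux <= 0) stop("`flux` must be positive")
  n_flats <- as.integer(n_flats)
  if (n_flats < 1L) stop("`n_flats` must be >= 1")
  subgroup <- ((seq_len(n_columns) - 1L) %% 4L) + 1L
  E <- matrix(flux * scheme$R[subgroup], ny, n_columns, byrow = TRUE)
  one_stack <- function(stream) {
    a <- array(0, dim = c(n_flats, ny, n_columns))
    for (f in seq_len(n_flats)) {
      a[f, , ] <- if (noise) {
        set.seed(frame_seed(seed, stream, f))
        stats::rpois(length(E), E)
      } else E
    }
    a
  }
  list(before = one_stack(2L), after = one_stack(3L))
}

#' @export
print.scan_frames <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "<scan_frames> %d frames x %d rows x %d columns (%d per subgroup); scan step %g um; flux %g; seed %d; %s\n",
    d[1], d[2], d[3], d[3] %/% 4L, x$scan_step, x$flux_per_frame, x$seed,
    if (x$noise) "Poisson noise" else "noise-free"))
  invisible(x)
}
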