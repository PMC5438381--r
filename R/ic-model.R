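# Illumination-curve model -----------------------------------------------
#
# The illumination curve (IC) is the bell-shaped response of one detector
# column to a lateral displacement of the pre-sample mask M1.  An object
# modifies it in three ways: attenuation scales it, refraction shifts it,
# and sub-pixel scattering broadens it.  The retrieval operates only on the
# local value R, slope R' and curvature R'' of the IC at the four sampling
# points of the asymmetric acquisition, so the IC enters everywhere through
# `ic_eval()`.

#' Construct a parametric illumination curve
#'
#' Builds a symmetric bell-shaped illumination curve (IC) on a pedestal.
#' Two functional forms are available:
#' \describe{
#'   \item{`"gaussian"`}{`R(phi) = baseline + (peak - baseline) *
#'     exp(-(phi - center)^2 / (2 * width^2))`. The default laboratory-source
#'     approximation; infinitely supported.}
#'   \item{`"cos2"`}{a raised-cosine bell with the same full width at half
#'     maximum as the Gaussian of equal `width`:
#'     `R(phi) = baseline + (peak - baseline) * cos^2(pi * u / (2 * U))` for
#'     `|u| < U`, `baseline` outside, with `u = phi - center` and
#'     `U = 2 * sqrt(2 * log(2)) * width`. Its flanks have zero curvature
#'     exactly at the half-maximum points, which is the regime assumed by the
#'     closed-form four-point retrieval (see `vignette("edge-illumination-multimodal")`).}
#' }
#'
#' @param peak_amplitude IC value at its maximum, dimensionless fraction in
#'   (0, 1]. Must exceed `baseline`.
#' @param width IC width parameter, in units of lateral M1 displacement
#'   (micrometres at the M1 plane). For both shapes the FWHM above the
#'   pedestal is `2 * sqrt(2 * log(2)) * width`.
#' @param baseline pedestal (transmission through the mask septa),
#'   dimensionless, `>= 0` and `< peak_amplitude`.
#' @param center displacement of the IC maximum (micrometres).
#' @param shape `"gaussian"` (default) or `"cos2"`.
#' @return An object of class `illumination_curve`.
#' @seealso [ic_eval()], [place_half_max_scheme()], [scheme_from_shifts()]
#' @examples
#' ic <- make_ic(1, 12.7, baseline = 0.01)
#' ic_eval(ic, 0)
#' @export
make_ic <- function(peak_amplitude, width, baseline = 0, center = 0,
                    shape = c("gaussian", "cos2")) {
  shape <- match.arg(shape)
  if (!is.numeric(peak_amplitude) || length(peak_amplitude) != 1L ||
      !is.finite(peak_amplitude) || peak_amplitude <= 0 || peak_amplitude > 1)
    stop("`peak_amplitude` must be a single finite value in (0, 1]")
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) ||
      width <= 0)
    stop("`width` must be a single positive finite value")
  if (!is.numeric(baseline) || length(baseline) != 1L || !is.finite(baseline) ||
      baseline < 0)
    stop("`baseline` must be a single finite value >= 0")
  if (baseline >= peak_amplitude)
    stop("`baseline` must be smaller than `peak_amplitude`")
  if (!is.numeric(center) || length(center) != 1L || !is.finite(center))
    stop("`center` must be a single finite value")
  structure(
    list(peak_amplitude = as.numeric(peak_amplitude),
         width = as.numeric(width),
         baseline = as.numeric(baseline),
         center = as.numeric(center),
         shape = shape),
    class = "illumination_curve")
}

#' @export
print.illumination_curve <- function(x, ...) {
  cat(sprintf(
    "<illumination_curve> shape=%s peak=%g baseline=%g width=%g um center=%g um\n",
    x$shape, x$peak_amplitude, x$baseline, x$width, x$center))
  invisible(x)
}

# FWHM of the bell above the pedestal, shared by both shapes.
ic_fwhm <- function(ic) 2 * sqrt(2 * log(2)) * ic$width

#' Evaluate an illumination curve and its derivatives
#'
#' Returns the IC value and its first and second analytic derivatives with
#' respect to mask displacement, the three quantities (R, R', R'') entering
#' the second-order Taylor forward model and the closed-form retrieval.
#'
#' @param ic an [illumination_curve][make_ic].
#' @param phi numeric vector of mask displacements (micrometres).
#' @return A list with numeric components `R`, `Rd` (first derivative,
#'   1/um) and `Rdd` (second derivative, 1/um^2), each the length of `phi`.
#' @examples
#' ic <- make_ic(1, 10)
#' ic_eval(ic, c(-5, 0, 5))
#' @export
ic_eval <- function(ic, phi) {
  stopifnot(inherits(ic, "illumination_curve"), is.numeric(phi))
  u <- phi - ic$center
  A <- ic$peak_amplitude - ic$baseline
  if (ic$shape == "gaussian") {
    w2 <- ic$width^2
    e <- exp(-u^2 / (2 * w2))
    list(R = ic$baseline + A * e,
         Rd = -A * u * e / w2,
         Rdd = A * e * (u^2 / w2^2 - 1 / w2))
  } else {
    U <- ic_fwhm(ic)                      # full support half-width
    a <- pi / (2 * U)
    inside <- abs(u) < U
    R <- rep(ic$baseline, length(u))
    Rd <- Rdd <- numeric(length(u))
    ui <- u[inside]
    R[inside] <- ic$baseline + A * cos(a * ui)^2
    Rd[inside] <- -A * a * sin(2 * a * ui)
    Rdd[inside] <- -2 * A * a^2 * cos(2 * a * ui)
    list(R = R, Rd = Rd, Rdd = Rdd)
  }
}

# Sampling scheme ---------------------------------------------------------

# Internal constructor: absolute sampling positions must be pair-symmetric
# about the IC center (positions 1/4 and 2/3 mirror each other); this is the
# assumption under which the closed-form retrieval is derived.
new_sampling_scheme <- function(ic, positions, tol = 1e-9) {
  stopifnot(length(positions) == 4L, !is.unsorted(positions))
  off <- positions - ic$center
  scale <- max(abs(off), ic$width)
  if (abs(off[1L] + off[4L]) > tol * scale ||
      abs(off[2L] + off[3L]) > tol * scale)
    stop("sampling points are not pair-symmetric about the IC center; ",
         "the closed-form retrieval requires offsets {-b, -a, a, b}")
  if (off[4L] <= off[3L] || off[3L] <= 0)
    stop("degenerate sampling scheme: the four points must be distinct, ",
         "two on each side of the IC center")
  ev <- ic_eval(ic, positions)
  # numeric consequences of symmetry, enforced at construction
  if (abs(ev$R[1L] - ev$R[4L]) > 1e-9 * ic$peak_amplitude ||
      abs(ev$R[2L] - ev$R[3L]) > 1e-9 * ic$peak_amplitude)
    stop("IC values at mirrored points differ; IC is not symmetric")
  structure(
    list(positions = positions, offsets = off,
         R = ev$R, Rd = ev$Rd, Rdd = ev$Rdd, ic = ic),
    class = "sampling_scheme")
}

#' @export
print.sampling_scheme <- function(x, ...) {
  cat("<sampling_scheme> 4 IC points (offsets relative to IC center, um):\n")
  print(data.frame(j = 1:4, offset = x$offsets, R = x$R,
                   Rd = x$Rd, Rdd = x$Rdd))
  invisible(x)
}

#' Place the four sampling points with the outer pair at half maximum
#'
#' Finds the displacement at which the IC falls to 50% of its maximum above
#' the pedestal (by root finding, so any symmetric bell behind the
#' [ic_eval()] contract works), puts sampling points 1 and 4 there, and the
#' inner pair 2 and 3 at `inner_fraction` of that offset.
#'
#' @param ic an [illumination_curve][make_ic].
#' @param inner_fraction position of the inner pair as a fraction of the
#'   outer-pair offset, strictly between 0 and 1. The default 1/3
#'   reproduces the printed aperture-shift layout `{-s, 0, s, 2s}` after
#'   symmetrization (offsets `{-3s/2, -s/2, s/2, 3s/2}`).
#' @return A `sampling_scheme` with points ordered by ascending offset.
#' @examples
#' sch <- place_half_max_scheme(make_ic(1, 10))
#' sch$offsets   # outer pair at +/- half of the FWHM
#' @export
place_half_max_scheme <- function(ic, inner_fraction = 1 / 3) {
  stopifnot(inherits(ic, "illumination_curve"))
  if (!is.numeric(inner_fraction) || length(inner_fraction) != 1L ||
      !is.finite(inner_fraction) || inner_fraction <= 0 || inner_fraction >= 1)
    stop("`inner_fraction` must lie strictly between 0 and 1 ",
         "(1 would collapse the scheme to two distinct points)")
  half <- ic$baseline + 0.5 * (ic$peak_amplitude - ic$baseline)
  upper <- if (ic$shape == "cos2") ic_fwhm(ic) * (1 - 1e-12) else 20 * ic$width
  f <- function(d) ic_eval(ic, ic$center + d)$R - half
  if (f(upper) >= 0)
    stop("root finding for the half-maximum point failed: IC does not ",
         "drop below 50% of its maximum within the search interval")
  d <- stats::uniroot(f, c(0, upper), tol = 1e-13 * ic$width)$root
  # Newton polish so that R(outer) hits the half level to ~machine precision
  for (i in 1:3) {
    ev <- ic_eval(ic, ic$center + d)
    if (ev$Rd == 0) break
    d <- d - (ev$R - half) / ev$Rd
  }
  new_sampling_scheme(ic, ic$center + c(-d, -inner_fraction * d,
                                        inner_fraction * d, d))
}

#' Build a sampling scheme from printed aperture-subgroup shifts
#'
#' Converts the lateral shifts of the M1 aperture subgroups (for example the
#' printed `{-s, 0, s, 2s}` with `s = 10` um) into IC sampling offsets. The
#' shifts as printed are not symmetric about zero, while the retrieval
#' formulas assume pair-symmetric sampling; a global alignment offset
#' (equivalently, a choice of IC-center position) restores the symmetry.
#' With shifts `{-s, 0, s, 2s}` and `global_offset = -s/2` the offsets
#' become `{-3s/2, -s/2, +s/2, +3s/2}`.
#'
#' @param ic an [illumination_curve][make_ic].
#' @param shifts numeric vector of 4 subgroup shifts (micrometres).
#' @param global_offset rigid lateral alignment offset added to all shifts
#'   (micrometres).
#' @param tol relative symmetry tolerance.
#' @return A `sampling_scheme`.
#' @examples
#' ic <- make_ic(1, 15 / sqrt(2 * log(2)))
#' scheme_from_shifts(ic, c(-10, 0, 10, 20), global_offset = -5)$offsets
#' @export
scheme_from_shifts <- function(ic, shifts, global_offset = 0, tol = 1e-9) {
  stopifnot(inherits(ic, "illumination_curve"))
  if (!is.numeric(shifts) || length(shifts) != 4L || anyNA(shifts))
    stop("`shifts` must be 4 finite subgroup shifts in micrometres")
  if (max(shifts) == min(shifts))
    stop("all subgroup shifts are equal: no asymmetry, the four points ",
         "coincide on the IC")
  off <- sort(shifts + global_offset - ic$center)
  scale <- max(abs(off))
  if (abs(off[1L] + off[4L]) > tol * scale ||
      abs(off[2L] + off[3L]) > tol * scale)
    stop("shifted sampling points are not pair-symmetric about the IC ",
         "center; adjust `global_offset` (the retrieval formulas assume ",
         "symmetric sampling)")
  new_sampling_scheme(ic, ic$center + off, tol = tol)
}
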