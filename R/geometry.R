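# Cone-beam geometry of the two-mask edge-illumination system ------------

#' System geometry of the scanning EI setup
#'
#' Distances are measured from the x-ray source along the optical axis.
#' The defaults reproduce the laboratory prototype: pre-sample mask M1 at
#' 1.5 m, detector mask M2 at 1.95 m, detector at 2 m, 100 um square
#' pixels, ~80 um focal spot.
#'
#' @param z_m1 source to pre-sample-mask distance (m).
#' @param z_m2 source to detector-mask distance (m).
#' @param z_det source to detector distance (m).
#' @param detector_pitch detector pixel pitch (um).
#' @param focal_spot focal spot size (um). Its blurring of the IC is folded
#'   into the IC width parameter rather than modelled by explicit source
#'   convolution; the value is carried for provenance.
#' @param z_sample source to sample distance (m); the sample sits between
#'   M1 and M2, by default immediately downstream of M1.
#' @return An object of class `system_geometry`.
#' @export
system_geometry <- function(z_m1 = 1.5, z_m2 = 1.95, z_det = 2.0,
                            detector_pitch = 100, focal_spot = 80,
                            z_sample = z_m1) {
  vals <- c(z_m1 = z_m1, z_m2 = z_m2, z_det = z_det,
            detector_pitch = detector_pitch, focal_spot = focal_spot,
            z_sample = z_sample)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all geometry parameters must be positive finite numbers")
  if (!(z_m1 < z_m2 && z_m2 <= z_det))
    stop("geometry must satisfy 0 < z_m1 < z_m2 <= z_det")
  if (z_sample < z_m1 || z_sample >= z_m2)
    stop("the sample must sit between the masks: z_m1 <= z_sample < z_m2")
  structure(as.list(vals), class = "system_geometry")
}

#' @export
print.system_geometry <- function(x, ...) {
  cat(sprintf(
    "<system_geometry> M1 %.3g m | sample %.3g m | M2 %.3g m | detector %.3g m; pixel %.4g um; focal spot %.3g um\n",
    x$z_m1, x$z_sample, x$z_m2, x$z_det, x$detector_pitch, x$focal_spot))
  invisible(x)
}

#' Mask specification
#'
#' @param pitch mask period (um).
#' @param aperture aperture opening (um), smaller than `pitch`.
#' @param subgroup_shifts optional lateral shifts of the aperture subgroups
#'   (um); for the asymmetric pre-sample mask the printed layout is
#'   `c(-10, 0, 10, 20)` (i.e. `-s, 0, s, 2s` with `s = 10` um).
#' @param label `"M1"` or `"M2"`.
#' @return An object of class `mask_spec`.
#' @export
mask_spec <- function(pitch, aperture, subgroup_shifts = NULL,
                      label = c("M1", "M2")) {
  label <- match.arg(label)
  if (!is.numeric(pitch) || pitch <= 0 || !is.numeric(aperture) ||
      aperture <= 0 || aperture >= pitch)
    stop("mask must satisfy 0 < aperture < pitch")
  if (!is.null(subgroup_shifts)) {
    if (!is.numeric(subgroup_shifts) || anyNA(subgroup_shifts))
      stop("`subgroup_shifts` must be finite numeric")
  }
  structure(list(pitch = pitch, aperture = aperture,
                 subgroup_shifts = subgroup_shifts,
                 n_subgroups = length(subgroup_shifts), label = label),
            class = "mask_spec")
}

#' Cone-beam projected pitch at the detector plane
#'
#' A mask of period `mask_pitch` at distance `z_mask` from the source
#' projects onto the detector plane at `z_det` with period
#' `mask_pitch * z_det / z_mask`. The prototype's masks were designed so
#' that this projection matches the 100 um detector pixels.
#'
#' @param mask_pitch mask period (um).
#' @param z_mask source to mask distance (m).
#' @param z_det source to detector distance (m).
#' @return projected period (um).
#' @examples
#' projected_pitch(75, 1.5, 2)     # 100
#' projected_pitch(97.5, 1.95, 2)  # 100
#' @export
projected_pitch <- function(mask_pitch, z_mask, z_det) {
  if (any(z_mask <= 0)) stop("`z_mask` must be positive")
  if (any(z_det < z_mask)) stop("mask must be upstream of the detector")
  mask_pitch * z_det / z_mask
}

#' Detector pitch demagnified to a mask plane
#'
#' Inverse design rule of [projected_pitch()]: the mask period whose
#' cone-beam projection at the detector equals the detector pixel pitch.
#'
#' @param detector_pitch detector pixel pitch (um).
#' @inheritParams projected_pitch
#' @return demagnified period (um).
#' @examples
#' demagnified_pitch(100, 1.5, 2)   # 75
#' demagnified_pitch(100, 1.95, 2)  # 97.5
#' @export
demagnified_pitch <- function(detector_pitch, z_mask, z_det) {
  if (any(z_det <= 0)) stop("`z_det` must be positive")
  if (any(z_mask <= 0) || any(z_mask > z_det))
    stop("mask must lie between source and detector")
  detector_pitch * z_mask / z_det
}

#' Convert a refraction angle to an IC displacement
#'
#' A beamlet refracted by `angle_rad` at the sample plane is laterally
#' displaced by `angle_rad * (z_m2 - z_sample)` when it reaches the
#' detector mask M2. The IC is parametrized in units of M1 displacement, so
#' the M2-plane displacement is divided by the M1-to-M2 magnification
#' `z_m2 / z_m1`.
#'
#' @param angle_rad refraction angle (rad), vectorized.
#' @param geom a [system_geometry()].
#' @param z_sample source to sample distance (m); defaults to the
#'   geometry's sample plane.
#' @return equivalent M1 displacement (um).
#' @examples
#' g <- system_geometry()
#' refraction_to_displacement(1e-6, g)  # 1 urad lever arm
#' @export
refraction_to_displacement <- function(angle_rad, geom,
                                       z_sample = geom$z_sample) {
  stopifnot(inherits(geom, "system_geometry"))
  if (z_sample < geom$z_m1 || z_sample >= geom$z_m2)
    stop("the sample must sit between the masks: z_m1 <= z_sample < z_m2")
  disp_m2_um <- angle_rad * (geom$z_m2 - z_sample) * 1e6
  disp_m2_um / (geom$z_m2 / geom$z_m1)
}

#' Lever arm mapping refraction angles to M1 displacements
#'
#' Scalar factor `g` (um per rad) such that an object refraction angle of
#' `x` rad shifts the working point on the IC by `g * x` um of equivalent
#' M1 displacement; scattering variances in rad^2 map by `g^2`.
#'
#' @inheritParams refraction_to_displacement
#' @return micrometres of M1 displacement per radian of refraction.
#' @export
displacement_per_radian <- function(geom, z_sample = geom$z_sample) {
  refraction_to_displacement(1, geom, z_sample)
}

#' Scan step of the object translation
#'
#' Object displacement between consecutive detector frames,
#' `1000 * speed / frame_rate` um. The exact quotient is returned: at the
#' prototype's printed 2.5 mm/s and 32 Hz this is 78.125 um per frame,
#' slightly coarser than the nominal 75 um effective pixel quoted for the
#' same acquisition.
#'
#' @param speed scan speed (mm/s).
#' @param frame_rate detector frame rate (Hz).
#' @return scan step (um per frame).
#' @examples
#' scan_step(2.5, 32)  # 78.125
#' scan_step(2.4, 32)  # 75
#' @export
scan_step <- function(speed, frame_rate) {
  if (!is.numeric(speed) || !is.numeric(frame_rate) ||
      any(speed <= 0) || any(frame_rate <= 0))
    stop("`speed` and `frame_rate` must be positive")
  1000 * speed / frame_rate
}
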