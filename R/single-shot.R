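# Single-image phase retrieval (homogeneous-object mode) ------------------
#
# Using only the image acquired by beamlet 1 (on the IC slope), absorption
# and refraction are coupled through a single thickness variable t(x, y)
# when the object is quasi-homogeneous with a fixed delta/beta ratio.
# Linearizing the IC about the sampling point,
#     m = I_1 / R_1 = u * (1 + (R'_1/R_1) * g * delta * t_x)
# with u = exp(-mu t), mu = 2 k beta, and t_x the thickness x-gradient.
# Because u' = -mu t_x u this is a first-order linear filter,
#     m = u - a u',   a = (R'_1/R_1) * g * (delta/beta) * lambda / (4 pi),
# inverted row by row in Fourier space (u_hat = m_hat / (1 - i a kappa)).
# The phase map follows without knowing beta itself:
#     Phi = -k delta t = (delta / (2 beta)) * log u   (radians, <= 0).

#' Single-image phase map of a quasi-homogeneous object
#'
#' @param I1 normalized image from IC point 1 (vacuum level `R_1`), a
#'   `ny x nx` matrix with x along columns.
#' @param scheme the `sampling_scheme`; point 1 must sit on the IC slope.
#' @param delta_beta delta/beta ratio of the assumed homogeneous material
#'   (must be positive; ~500 for soft tissue / plastics at these energies).
#' @param energy_kev design x-ray energy (keV), sets the wavelength in the
#'   absorption/refraction coupling length.
#' @param pixel_size object pixel size along x (um).
#' @param disp_per_rad geometry lever arm (um of M1 displacement per rad of
#'   refraction, see [displacement_per_radian()]).
#' @param u_floor positivity floor applied to the recovered attenuation
#'   factor before taking the logarithm.
#' @return `ny x nx` matrix of phase shifts (rad, 0 in vacuum, negative in
#'   the object), with attribute `"n_floored"` counting clipped pixels.
#' @export
retrieve_single_shot <- function(I1, scheme, delta_beta, energy_kev = 50,
                                 pixel_size, disp_per_rad,
                                 u_floor = 1e-9) {
  stopifnot(inherits(scheme, "sampling_scheme"), is.matrix(I1))
  if (!is.numeric(delta_beta) || length(delta_beta) != 1L ||
      delta_beta <= 0)
    stop("`delta_beta` must be a single positive number")
  R1 <- scheme$R[1L]; Rd1 <- scheme$Rd[1L]
  if (abs(Rd1) < 1e-12 * scheme$ic$peak_amplitude / scheme$ic$width)
    stop("IC point 1 sits at an extremum (zero slope); single-shot ",
         "retrieval needs a sloped working point")
  if (pixel_size <= 0 || disp_per_rad <= 0)
    stop("`pixel_size` and `disp_per_rad` must be positive")
  lambda_um <- 1.23984193e-3 / energy_kev
  a <- (Rd1 / R1) * disp_per_rad * delta_beta * lambda_um / (4 * pi)  # um
  m <- I1 / R1
  m[!is.finite(m)] <- 1
  ny <- nrow(m); nx <- ncol(m)
  # mirror-pad along x to a power of two to suppress wrap-around
  n2 <- 2^ceiling(log2(2L * nx))
  pad <- n2 - nx
  lpad <- pad %/% 2L; rpad <- pad - lpad
  lidx <- if (lpad > 0) pmin(lpad:1, nx) else integer(0)
  ridx <- if (rpad > 0) pmax(nx - (1:rpad) + 1L, 1L) else integer(0)
  kappa <- 2 * pi * c(0:(n2 %/% 2L), -((n2 - n2 %/% 2L - 1L):1)) /
    (n2 * pixel_size)
  H <- 1 / (1 - 1i * a * kappa)
  u <- matrix(0, ny, nx)
  for (r in seq_len(ny)) {
    row <- c(m[r, lidx], m[r, ], m[r, ridx])
    uhat <- stats::fft(row) * H
    u[r, ] <- Re(stats::fft(uhat, inverse = TRUE) / n2)[lpad + seq_len(nx)]
  }
  n_floored <- sum(u < u_floor)
  u <- pmax(u, u_floor)
  phase <- 0.5 * delta_beta * log(u)
  attr(phase, "n_floored") <- n_floored
  phase
}
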