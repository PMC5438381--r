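# Multimodal retrieval ----------------------------------------------------
#
# Inverse pipeline: per-column flat-fielding, shift-and-add assembly of the
# four subgroup images on a common object grid, and closed-form inversion
# of the second-order IC Taylor model into absorption, DPC and dark-field.

#' Flat-field a scan
#'
#' Normalizes the raw counts column by column against the mean of the
#' before/after flat stacks, rescaled by the subgroup's IC value so that a
#' no-sample region maps to `R_j` (the normalization under which the
#' closed-form retrieval returns transmission 1 in vacuum). Columns whose
#' flat reference is non-positive or non-finite are masked and propagate
#' as `NA`, never as zeros.
#'
#' @param frames a [scan_frames][simulate_scan] object, or any list with
#'   the same fields (externally acquired stacks can be wrapped with
#'   [read_frames()]).
#' @return list with `normalized` (`n_frames x ny x n_columns` array),
#'   `column_mask` (logical, `TRUE` = usable) and `flat_reference`.
#' @export
flat_field <- function(frames) {
  counts <- frames$counts
  d <- dim(counts)
  flat_ref <- (apply(frames$flats_before, c(2L, 3L), mean) +
                 apply(frames$flats_after, c(2L, 3L), mean)) / 2
  column_mask <- apply(flat_ref > 0 & is.finite(flat_ref), 2L, all)
  Rj <- frames$scheme$R[frames$column_subgroup]
  scale <- sweep(1 / flat_ref, 2L, Rj, "*")   # ny x C
  scale[!is.finite(scale)] <- NA_real_
  scale[, !column_mask] <- NA_real_
  normalized <- counts *
    aperm(array(scale, dim = c(d[2L], d[3L], d[1L])), c(3L, 1L, 2L))
  list(normalized = normalized, column_mask = column_mask,
       flat_reference = flat_ref)
}

#' Assemble the four subgroup images
#'
#' Columns belonging to the same aperture subgroup view the object at known
#' relative x offsets (one column spacing per `spacing_steps` scan steps).
#' Their frame series are translated onto the common object grid and
#' averaged, increasing statistics by the number of contributing columns
#' (32 per subgroup with the prototype's 128 columns). Integer offsets use
#' exact shifts; fractional offsets require `interpolate = TRUE` (linear
#' interpolation between adjacent frames) and otherwise raise an error.
#'
#' @param normalized `n_frames x ny x n_columns` array of flat-fielded
#'   intensities (see [flat_field()]).
#' @param column_subgroup integer vector of subgroup labels 1..4 per column.
#' @param spacing_steps column spacing in scan steps (may be fractional
#'   with `interpolate = TRUE`).
#' @param scheme the `sampling_scheme` the columns were acquired on.
#' @param interpolate allow linear interpolation for non-commensurate
#'   offsets.
#' @return An object of class `subgroup_images`: list with `I` (list of 4
#'   `ny x nx` matrices ordered by IC point), `n_summed` (contributing
#'   columns per subgroup) and `scheme`.
#' @export
assemble_subgroups <- function(normalized, column_subgroup,
                               spacing_steps = 1, scheme,
                               interpolate = FALSE) {
  d <- dim(normalized)
  if (length(d) != 3L) stop("`normalized` must be n_frames x ny x n_columns")
  n_frames <- d[1L]; ny <- d[2L]; n_col <- d[3L]
  if (length(column_subgroup) != n_col)
    stop("`column_subgroup` must have one label per column")
  if (!all(column_subgroup %in% 1:4))
    stop("subgroup labels must be in 1..4")
  if (length(unique(tabulate(column_subgroup, 4L))) != 1L)
    stop("every subgroup must contain the same number of columns")
  integral <- abs(spacing_steps - round(spacing_steps)) < 1e-9
  if (!integral && !interpolate)
    stop("column offsets are not integer multiples of the scan step; ",
         "set `interpolate = TRUE` to enable linear interpolation")
  nx <- n_frames - as.integer(ceiling((n_col - 1L) * spacing_steps))
  if (nx < 1L) stop("frame stack too short for this column layout")
  I <- vector("list", 4L)
  n_summed <- integer(4L)
  for (j in 1:4) {
    cols <- which(column_subgroup == j)
    acc <- matrix(0, ny, nx)
    wt <- matrix(0, ny, nx)
    for (cc in cols) {
      fidx <- seq_len(nx) + (cc - 1L) * spacing_steps
      if (integral) {
        slab <- matrix(normalized[round(fidx), , cc], nrow = ny,
                       byrow = TRUE)
      } else {
        f0 <- floor(fidx); w1 <- fidx - f0
        slab <- matrix((1 - w1) * normalized[f0, , cc] +
                         w1 * normalized[f0 + 1L, , cc],
                       nrow = ny, byrow = TRUE)
      }
      ok <- is.finite(slab)
      slab[!ok] <- 0
      acc <- acc + slab
      wt <- wt + ok
    }
    img <- acc / wt
    img[wt == 0] <- NA_real_
    I[[j]] <- img
    n_summed[j] <- length(cols)
  }
  structure(list(I = I, n_summed = n_summed, scheme = scheme),
            class = "subgroup_images")
}

#' @export
print.subgroup_images <- function(x, ...) {
  cat(sprintf(
    "<subgroup_images> 4 images of %d x %d pixels; %s columns summed per subgroup\n",
    nrow(x$I[[1]]), ncol(x$I[[1]]),
    paste(x$n_summed, collapse = "/")))
  invisible(x)
}

#' Closed-form four-point multimodal retrieval
#'
#' Pixel-wise inversion of the four normalized subgroup images under the
#' second-order IC Taylor model, assuming small refraction and dark-field
#' angles and pair-symmetric sampling with the outer points at 50% of the
#' IC maximum:
#' \deqn{I_R = \frac{1}{2}\frac{I_1+I_2+I_3+I_4}{R_1+R_2}}
#' \deqn{\Delta\varphi_R = \frac{(I_1+I_2)-(I_3+I_4)}{I_1+I_2+I_3+I_4}
#'       \cdot \frac{R_1+R_2}{\dot R_1+\dot R_2}}
#' \deqn{\sigma^2 = 2\,\frac{R_1(I_2+I_3)-R_2(I_1+I_4)}
#'       {\ddot R_2 (I_1+I_4)} - \Delta\varphi_R^2}
#'
#' DPC and dark-field are returned in IC-displacement units (um and um^2 at
#' the M1 plane); divide by the geometry lever arm
#' ([displacement_per_radian()]) and its square to convert to rad and
#' rad^2. Dark-field values may be negative under noise; they are reported
#' unclipped, with a `bad` mask flagging pixels lost to zero denominators
#' or missing inputs.
#'
#' @param sub a [subgroup_images][assemble_subgroups] object.
#' @return An object of class `retrieved_images`: matrices `absorption`,
#'   `dpc`, `darkfield`, logical matrix `bad`, count `n_bad`, and the
#'   `scheme`.
#' @seealso [retrieve_multimodal_ls()] for the independent least-squares
#'   inversion of the same forward model.
#' @export
retrieve_multimodal <- function(sub) {
  stopifnot(inherits(sub, "subgroup_images"))
  sch <- sub$scheme
  I1 <- sub$I[[1]]; I2 <- sub$I[[2]]; I3 <- sub$I[[3]]; I4 <- sub$I[[4]]
  S <- I1 + I2 + I3 + I4
  S14 <- I1 + I4
  bad <- !is.finite(S) | S == 0 | !is.finite(S14) | S14 == 0
  if (abs(sch$Rd[1] + sch$Rd[2]) == 0)
    stop("degenerate scheme: zero summed slope at points 1 and 2")
  absorption <- 0.5 * S / (sch$R[1] + sch$R[2])
  dpc <- ((I1 + I2) - (I3 + I4)) / S * (sch$R[1] + sch$R[2]) /
    (sch$Rd[1] + sch$Rd[2])
  darkfield <- 2 * (sch$R[1] * (I2 + I3) - sch$R[2] * S14) /
    (sch$Rdd[2] * S14) - dpc^2
  absorption[bad] <- NA_real_
  dpc[bad] <- NA_real_
  darkfield[bad] <- NA_real_
  structure(list(absorption = absorption, dpc = dpc, darkfield = darkfield,
                 bad = bad, n_bad = sum(bad), scheme = sch,
                 phase_map = NULL),
            class = "retrieved_images")
}

#' Least-squares inversion of the forward model
#'
#' Independent numerical route to the same three channels: the second-order
#' Taylor model is linear in the parameters `(I_R, I_R * dphi, I_R * q)`
#' with `q = dphi^2 + sigma^2`, so the four subgroup intensities are
#' inverted pixel-wise by linear least squares on the design matrix
#' `[R_j, Rd_j, Rdd_j / 2]`. For data generated exactly by the forward
#' model this recovers the inputs to machine precision, making it the
#' reference oracle against which the closed-form approximation is
#' compared; it makes none of the closed form's small-signal assumptions.
#'
#' @inheritParams retrieve_multimodal
#' @return A `retrieved_images` object.
#' @export
retrieve_multimodal_ls <- function(sub) {
  stopifnot(inherits(sub, "subgroup_images"))
  sch <- sub$scheme
  A <- cbind(sch$R, sch$Rd, 0.5 * sch$Rdd)
  dims <- dim(sub$I[[1]])
  Im <- rbind(as.vector(sub$I[[1]]), as.vector(sub$I[[2]]),
              as.vector(sub$I[[3]]), as.vector(sub$I[[4]]))
  bad <- !apply(is.finite(Im), 2L, all)
  Im[, bad] <- 0
  P <- qr.coef(qr(A), Im)             # 3 x npix
  IR <- P[1L, ]
  bad <- bad | !is.finite(IR) | IR == 0
  dphi <- P[2L, ] / IR
  q <- P[3L, ] / IR
  s2 <- q - dphi^2
  IR[bad] <- dphi[bad] <- s2[bad] <- NA_real_
  structure(list(absorption = matrix(IR, dims[1L], dims[2L]),
                 dpc = matrix(dphi, dims[1L], dims[2L]),
                 darkfield = matrix(s2, dims[1L], dims[2L]),
                 bad = matrix(bad, dims[1L], dims[2L]), n_bad = sum(bad),
                 scheme = sch, phase_map = NULL),
            class = "retrieved_images")
}

#' @export
print.retrieved_images <- function(x, ...) {
  if (!is.null(x$absorption)) {
    cat(sprintf(
      "<retrieved_images> %d x %d pixels; %d flagged; mean absorption %.4g; dpc in [%.3g, %.3g] um; darkfield in [%.3g, %.3g] um^2\n",
      nrow(x$absorption), ncol(x$absorption), x$n_bad,
      mean(x$absorption, na.rm = TRUE),
      min(x$dpc, na.rm = TRUE), max(x$dpc, na.rm = TRUE),
      min(x$darkfield, na.rm = TRUE), max(x$darkfield, na.rm = TRUE)))
  } else {
    cat(sprintf("<retrieved_images> single-shot phase map %d x %d pixels\n",
                nrow(x$phase_map), ncol(x$phase_map)))
  }
  invisible(x)
}

#' Run the full inverse pipeline on a frame stack
#'
#' Convenience wrapper: [flat_field()], [assemble_subgroups()], then either
#' the closed-form multimodal retrieval or the single-image phase map.
#' In multimodal mode the DPC and dark-field channels are additionally
#' converted back to angle units using the lever arm stored with the
#' frames (`dpc_urad`, `darkfield_urad2`).
#'
#' @param frames a [scan_frames][simulate_scan] object.
#' @param mode `"multimodal"` (default), `"multimodal_ls"` or
#'   `"single_shot"`.
#' @param delta_beta delta/beta ratio of the (assumed homogeneous) object,
#'   required for `mode = "single_shot"`.
#' @param energy_kev design energy for single-shot mode.
#' @param interpolate passed to [assemble_subgroups()].
#' @return A `retrieved_images` object.
#' @export
ei_retrieve <- function(frames, mode = c("multimodal", "multimodal_ls",
                                         "single_shot"),
                        delta_beta = NULL, energy_kev = 50,
                        interpolate = FALSE) {
  mode <- match.arg(mode)
  ff <- flat_field(frames)
  sub <- assemble_subgroups(ff$normalized, frames$column_subgroup,
                            frames$spacing_steps, frames$scheme,
                            interpolate = interpolate)
  if (mode == "single_shot") {
    if (is.null(delta_beta))
      stop("single-shot mode requires `delta_beta`")
    phase <- retrieve_single_shot(sub$I[[1L]], frames$scheme, delta_beta,
                                  energy_kev = energy_kev,
                                  pixel_size = frames$scan_step,
                                  disp_per_rad = frames$disp_per_rad)
    return(structure(list(absorption = NULL, dpc = NULL, darkfield = NULL,
                          bad = NULL, n_bad = 0L, scheme = frames$scheme,
                          phase_map = phase),
                     class = "retrieved_images"))
  }
  ret <- if (mode == "multimodal") retrieve_multimodal(sub)
         else retrieve_multimodal_ls(sub)
  g <- frames$disp_per_rad
  ret$dpc_urad <- ret$dpc / g * 1e6
  ret$darkfield_urad2 <- ret$darkfield / g^2 * 1e12
  ret$disp_per_rad <- g
  ret
}
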