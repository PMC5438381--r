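# shared fixtures -----------------------------------------------------------

# the laboratory default: Gaussian IC, outer points at +/-15 um (50% of max)
default_ic <- function(shape = "gaussian")
  make_ic(0.9, 15 / sqrt(2 * log(2)), baseline = 0.01, center = 0,
          shape = shape)

default_scheme <- function(shape = "gaussian")
  scheme_from_shifts(default_ic(shape), c(-10, 0, 10, 20),
                     global_offset = -5)

# forward model evaluated directly from a scheme on parameter triples
forward_I <- function(scheme, I_R, dphi, s2)
  vapply(1:4, function(j)
    I_R * (scheme$R[j] + scheme$Rd[j] * dphi +
             0.5 * scheme$Rdd[j] * (dphi^2 + s2)),
    numeric(length(I_R)))

# wrap per-pixel intensity quadruples as a subgroup_images object
as_subgroup <- function(I, scheme) {
  I <- matrix(I, ncol = 4L)
  structure(list(I = lapply(1:4, function(j) matrix(I[, j], nrow = 1L)),
                 n_summed = rep(1L, 4L), scheme = scheme),
            class = "subgroup_images")
}

vacuum_phantom <- function(nx = 40, ny = 2, pixel_size = 75)
  generate_phantom(list(), nx = nx, ny = ny, pixel_size = pixel_size)
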