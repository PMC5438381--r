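test_that("empty phantom is vacuum", {
  ph <- vacuum_phantom(nx = 12, ny = 3)
  expect_true(all(ph$transmission == 1))
  expect_true(all(ph$refraction == 0))
  expect_true(all(ph$scatter_var == 0))
})

test_that("slab phantom: interior refraction vanishes, attenuation matches", {
  mat <- ei_material(1e-7, 2e-10, scatter = 3e-15)
  ph <- generate_phantom(list(shape_slab(-800, 800, 4000, mat)),
                         nx = 64, ny = 2, pixel_size = 75,
                         energy_kev = 50)
  x <- (seq_len(64) - 32.5) * 75
  interior <- which(x > -700 & x < 700)
  expect_true(all(ph$refraction[, interior] == 0))
  k <- 2 * pi / (1.23984193e-3 / 50)
  expect_equal(ph$transmission[1, interior[1]], exp(-2 * k * 2e-10 * 4000),
               tolerance = 1e-12)
  expect_equal(ph$scatter_var[1, interior[1]], 3e-15 * 4000)
})

test_that("cylinder refraction matches the analytic thickness derivative", {
  mat <- ei_material(1.06e-7, 2.2e-10)
  px <- 25; r <- 1500
  ph <- generate_phantom(list(shape_cylinder(0, r, mat)),
                         nx = 160, ny = 1, pixel_size = px)
  x <- (seq_len(160) - 80.5) * px
  # transmission symmetric, refraction antisymmetric about the axis
  expect_equal(ph$transmission[1, ], rev(ph$transmission[1, ]),
               tolerance = 1e-12)
  expect_equal(ph$refraction[1, ], -rev(ph$refraction[1, ]),
               tolerance = 1e-12)
  # analytic: d/dx [delta * 2 sqrt(r^2 - x^2)] = -2 delta x / sqrt(r^2-x^2)
  inner <- which(abs(x) < 0.7 * r)
  analytic <- -2 * mat$delta * x[inner] / sqrt(r^2 - x[inner]^2)
  # central differences of a curved profile: agree to the FD truncation
  expect_equal(ph$refraction[1, inner], analytic,
               tolerance = 5e-4)
})

test_that("transmission underflow is clipped with a warning", {
  mat <- ei_material(1e-7, 1e-5)
  expect_warning(
    ph <- generate_phantom(list(shape_slab(-3000, 3000, 5e4, mat)),
                           nx = 16, ny = 1, pixel_size = 500),
    "underflow")
  expect_true(all(ph$transmission >= 1e-12))
})

test_that("expected_intensity implements the second-order IC expansion", {
  sch <- default_scheme()
  for (j in 1:4) {
    expect_equal(as.numeric(expected_intensity(sch, j, 1, 0, 0)), sch$R[j])
    expect_equal(as.numeric(expected_intensity(sch, j, 0.5, 0, 0)),
                 0.5 * sch$R[j])
  }
  # matches the shifted IC directly to third order in dphi
  ic <- sch$ic
  err_at <- function(d) {
    direct <- ic_eval(ic, sch$positions[2] + d)$R
    abs(as.numeric(expected_intensity(sch, 2, 1, d, 0)) - direct)
  }
  # halving dphi must shrink the mismatch by ~2^3
  e1 <- err_at(2); e2 <- err_at(1)
  expect_lt(e2, e1 / 6)
  expect_lt(e1, 1e-3)
  # negative intensities are clipped and counted
  I <- expected_intensity(sch, 1, 1, -60, 0)
  expect_equal(as.numeric(I), 0)
  expect_equal(attr(I, "n_clipped"), 1L)
  expect_error(expected_intensity(sch, 5, 1, 0, 0), "IC points")
  expect_error(expected_intensity(sch, 1, 1, 0, -1), "variance")
})

test_that("simulate_scan is deterministic and exact in the noise-free limit", {
  ph <- vacuum_phantom(nx = 20, ny = 2)
  geom <- system_geometry()
  sch <- default_scheme()
  a <- simulate_scan(ph, geom, sch, 1e3, n_columns = 8, n_flats = 3,
                     seed = 99)
  b <- simulate_scan(ph, geom, sch, 1e3, n_columns = 8, n_flats = 3,
                     seed = 99)
  expect_identical(a$counts, b$counts)
  expect_identical(a$flats_before, b$flats_before)
  c2 <- simulate_scan(ph, geom, sch, 1e3, n_columns = 8, n_flats = 3,
                      seed = 100)
  expect_false(identical(a$counts, c2$counts))
  # vacuum, noise off: counts / flux = R_j for every column and frame
  nf <- simulate_scan(ph, geom, sch, 1e3, n_columns = 8, n_flats = 3,
                      noise = FALSE)
  Rj <- sch$R[nf$column_subgroup]
  for (cc in seq_len(8))
    expect_equal(as.numeric(nf$counts[, , cc] / 1e3),
                 rep(Rj[cc], prod(dim(nf$counts)[1:2])), tolerance = 1e-12)
  expect_error(simulate_scan(ph, geom, sch, -5), "positive")
  expect_error(simulate_scan(ph, geom, sch, 1e3, n_columns = 6),
               "multiple of 4")
})

test_that("Poisson statistics: mean matches the expectation, var ~ mean", {
  sch <- default_scheme()
  flux <- 500
  fl <- simulate_flats(sch, n_columns = 4, ny = 1, flux = flux,
                       n_flats = 4000, seed = 5)
  for (cc in 1:4) {
    draws <- fl$before[, 1, cc]
    expe <- flux * sch$R[cc]
    se <- sqrt(expe / length(draws))
    expect_lt(abs(mean(draws) - expe), 3.5 * se)
    expect_lt(abs(var(draws) / mean(draws) - 1), 0.1)
  }
  # before/after stacks come from different substreams
  expect_false(identical(fl$before, fl$after))
})

test_that("flat-fielded noise scales as 1/sqrt(flux)", {
  ph <- vacuum_phantom(nx = 60, ny = 4)
  geom <- system_geometry()
  sch <- default_scheme()
  rel_std <- function(flux, seed) {
    fr <- simulate_scan(ph, geom, sch, flux, n_columns = 8, n_flats = 400,
                        seed = seed)
    nrm <- flat_field(fr)$normalized
    # column 1's subgroup: normalized vacuum level is R_1
    sd(nrm[, , 1]) / mean(nrm[, , 1])
  }
  r1 <- rel_std(2e3, 21)
  r2 <- rel_std(8e3, 22)
  expect_lt(abs(r1 / r2 - 2), 0.1 * 2)
})
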