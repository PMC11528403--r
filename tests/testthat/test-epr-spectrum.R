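# independent direct convolution of a stick pattern, used as the oracle for
# the isotropic-g limit of the powder simulation
direct_stick_spectrum <- function(sys, field, linewidth_pp) {
  sticks <- stick_pattern(sys$couplings)
  g <- sys$g[1]
  centers <- resonance_field(g, sys$mw_ghz) + mhz_to_mT(sticks$offset_mhz, g)
  sigma <- linewidth_pp / 2
  y <- rowSums(vapply(seq_along(centers), function(k) {
    sticks$weight[k] * exp(-(field - centers[k])^2 / (2 * sigma^2))
  }, numeric(length(field))))
  y / sum(diff(field) * (head(y, -1) + tail(y, -1)) / 2)
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))

test_that("isotropic-g powder spectrum equals the direct stick convolution", {
  sys <- spin_system(c(2.004, 2.004, 2.004),
                     list(list(a_iso = 60, n = 1)), mw_ghz = 9.373)
  s <- powder_spectrum(sys, sim_config(n_orientations = 200, n_points = 2048))
  oracle <- direct_stick_spectrum(sys, s$field, 0.6)
  expect_lt(rel_l2(s$intensity, oracle), 1e-6)
})

test_that("powder grid convergence: doubling orientations barely moves the spectrum", {
  sys <- radical_spin_system("alanyl")
  s1 <- powder_spectrum(sys, sim_config(n_orientations = 10000))
  s2 <- powder_spectrum(sys, sim_config(n_orientations = 20000))
  expect_lt(rel_l2(s1$intensity, s2$intensity), 1e-3)
})

test_that("axial powder pattern spans the g-parallel to g-perpendicular fields", {
  sys <- spin_system(c(2.004, 2.002, 2.002), mw_ghz = 9.373)
  s <- powder_spectrum(sys, sim_config(n_orientations = 4000))
  peak_region <- s$field[s$intensity > 0.1 * max(s$intensity)]
  b_par <- resonance_field(2.004, 9.373)
  b_perp <- resonance_field(2.002, 9.373)
  expect_lt(min(peak_region), b_par + 0.6)
  expect_gt(max(peak_region), b_perp - 0.6)
})

test_that("derivative_spectrum is antisymmetric for a symmetric line", {
  field <- seq(-5, 5, length.out = 1001)
  gauss <- epr_spectrum(field + 100, exp(-field^2 / 2), mode = "absorption")
  d <- derivative_spectrum(gauss)
  # zero crossing at the centre, peak-to-peak separation 2*sigma
  expect_equal(d$intensity[501], 0, tolerance = 1e-8)
  pp <- d$field[which.max(d$intensity)] - d$field[which.min(d$intensity)]
  expect_equal(abs(pp), 2, tolerance = 0.05)
  expect_error(derivative_spectrum(d), "absorption")
  # constant absorption -> all-zero derivative
  flat <- derivative_spectrum(epr_spectrum(1:100, rep(2, 100), mode = "absorption"))
  expect_true(all(flat$intensity == 0))
})

test_that("double integration recovers a closed-form Gaussian area", {
  field <- seq(320, 350, length.out = 2048)
  sigma <- 0.4; center <- 334
  absorb <- exp(-(field - center)^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  d <- derivative_spectrum(epr_spectrum(field, absorb, mode = "absorption"))
  expect_equal(double_integral(d), 1, tolerance = 1e-3)
  # linearity and the zero spectrum
  d2 <- epr_spectrum(d$field, 2 * d$intensity, mode = "first_derivative")
  expect_equal(double_integral(d2) / double_integral(d), 2, tolerance = 1e-9)
  zero <- epr_spectrum(field, rep(0, length(field)), mode = "first_derivative")
  expect_equal(double_integral(zero), 0)
  expect_error(double_integral(epr_spectrum(1:5, rnorm(5), mode = "first_derivative")),
               "8 points")
})

test_that("double integral is invariant under field-axis resampling", {
  sys <- radical_spin_system("serinyl")
  s <- powder_spectrum(sys, fast_cfg(n_points = 2048))
  d <- derivative_spectrum(s)
  di_fine <- double_integral(d)
  # resample at half the points (still well above Nyquist for 0.6 mT lines)
  idx <- seq(1, 2048, by = 2)
  d_half <- epr_spectrum(d$field[idx], d$intensity[idx], mode = "first_derivative")
  expect_equal(double_integral(d_half) / di_fine, 1, tolerance = 1e-3)
})

test_that("spin_fraction handles identity and zero cases", {
  sys <- radical_spin_system("glycyl")
  d <- derivative_spectrum(powder_spectrum(sys, fast_cfg()))
  expect_equal(spin_fraction(d, d), 1)
  zero <- epr_spectrum(d$field, rep(0, nrow(d)), mode = "first_derivative")
  expect_equal(spin_fraction(zero, d), 0)
  expect_error(spin_fraction(d, zero), "positive")
})

test_that("spectrum text round trip preserves field, intensity and mode", {
  s <- powder_spectrum(radical_spin_system("glycyl"), fast_cfg())
  d <- derivative_spectrum(s)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(d, path)
  back <- read_spectrum(path)
  expect_equal(spectrum_mode(back), "first_derivative")
  expect_equal(back$field, d$field, tolerance = 1e-6)
  expect_equal(back$intensity, d$intensity, tolerance = 1e-8)
})

test_that("spin systems load from YAML configs", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "g: [1.999, 2.004, 2.007]",
    "couplings:",
    "  - {a_iso_mhz: 60, n: 3}",
    "mw_ghz: 9.373"
  ), path)
  sys <- read_spin_system(path)
  expect_equal(sys$g, c(1.999, 2.004, 2.007))
  expect_equal(sys$couplings[[1]]$a_iso, 60)
  expect_equal(sys$couplings[[1]]$n, 3)
  expect_equal(sys$mw_ghz, 9.373)
})
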