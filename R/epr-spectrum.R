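# CW EPR powder simulation for S = 1/2 radicals with rhombic g and isotropic
# 1H hyperfine. Orientations are averaged on a deterministic golden-spiral
# sphere grid; each orientation contributes its first-order stick pattern at
# the local effective g, and the accumulated sticks are convolved with a
# Gaussian (or Lorentzian) lineshape.

#' Define an S = 1/2 spin system
#'
#' @param g Length-3 numeric principal g-values (order free).
#' @param couplings List of isotropic 1H couplings, each
#'   `list(a_iso = <MHz>, n = <equivalent protons>)`.
#' @param mw_ghz Microwave frequency in GHz.
#' @return A list of class `spin_system`.
#' @examples
#' spin_system(g = c(1.999, 2.004, 2.007),
#'             couplings = list(list(a_iso = 60, n = 3)), mw_ghz = 9.373)
#' @export
spin_system <- function(g, couplings = list(), mw_ghz = 9.373) {
  g <- as.numeric(g)
  if (length(g) == 1L) g <- rep(g, 3L)
  if (length(g) != 3L || any(!is.finite(g)) || any(g <= 0)) {
    abort("`g` must be 3 positive finite values")
  }
  if (mw_ghz <= 0) abort("`mw_ghz` must be positive")
  structure(list(g = g, couplings = couplings, mw_ghz = mw_ghz),
            class = "spin_system")
}

#' Simulation configuration
#'
#' @param field_range Length-2 numeric (mT) or `NULL` to auto-range over all
#'   resonances plus five linewidths of margin.
#' @param n_points Number of field points (>= 64).
#' @param linewidth_pp Peak-to-peak Gaussian linewidth in mT (the
#'   peak-to-peak width of the first-derivative line; the underlying
#'   Gaussian has sigma = linewidth_pp / 2).
#' @param n_orientations Powder-grid size (golden-spiral points).
#' @param lineshape `"gaussian"` or `"lorentzian"`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(field_range = NULL, n_points = 1024,
                       linewidth_pp = 0.6, n_orientations = 10000,
                       lineshape = c("gaussian", "lorentzian")) {
  lineshape <- match.arg(lineshape)
  if (n_points < 64) abort("`n_points` must be >= 64")
  if (linewidth_pp <= 0) abort("`linewidth_pp` must be positive")
  if (n_orientations < 1) abort("`n_orientations` must be >= 1")
  structure(list(field_range = field_range, n_points = as.integer(n_points),
                 linewidth_pp = linewidth_pp,
                 n_orientations = as.integer(n_orientations),
                 lineshape = lineshape),
            class = "sim_config")
}

#' Construct a spectrum tibble
#'
#' @param field Strictly increasing field axis in mT.
#' @param intensity Intensities, same length as `field`.
#' @param mode `"absorption"` or `"first_derivative"`.
#' @return Tibble of class `epr_spectrum` with columns `field`, `intensity`.
#' @export
epr_spectrum <- function(field, intensity, mode = c("absorption", "first_derivative")) {
  mode <- match.arg(mode)
  if (length(field) != length(intensity)) abort("`field` and `intensity` lengths differ")
  if (any(diff(field) <= 0)) abort("`field` must be strictly increasing")
  structure(tibble(field = field, intensity = intensity),
            mode = mode, class = c("epr_spectrum", class(tibble())))
}

#' @rdname epr_spectrum
#' @param spectrum An `epr_spectrum`.
#' @export
spectrum_mode <- function(spectrum) attr(spectrum, "mode")

# unit-area deterministic sphere grid (golden spiral); returns direction
# cosines as an n x 3 matrix
golden_spiral <- function(n) {
  i <- seq_len(n)
  z <- (2 * i - 1) / n - 1
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Simulate a powder absorption spectrum
#'
#' Orientation-averages the first-order resonance over a deterministic
#' golden-spiral grid: at each orientation with direction cosines `l`,
#' the effective g is `sqrt(sum g_i^2 l_i^2)`; the hyperfine stick pattern is
#' converted to field units at that g and placed around the orientation's
#' resonance field; accumulated sticks are convolved with the lineshape.
#' The returned absorption is normalised to unit area (so intensities are
#' per-spin densities; scale as needed).
#'
#' @param sys A [spin_system()].
#' @param cfg A [sim_config()].
#' @param normalize Normalise the absorption to unit trapezoidal area
#'   (default `TRUE`).
#' @return An `epr_spectrum` in absorption mode.
#' @examples
#' s <- powder_spectrum(spin_system(c(2.004, 2.002, 2.002)),
#'                      sim_config(n_orientations = 2000, n_points = 512))
#' @export
powder_spectrum <- function(sys, cfg = sim_config(), normalize = TRUE) {
  stopifnot(inherits(sys, "spin_system"), inherits(cfg, "sim_config"))
  dirs <- golden_spiral(cfg$n_orientations)
  g_eff <- sqrt(drop(dirs^2 %*% sys$g^2))
  centers <- resonance_field(g_eff, sys$mw_ghz)
  sticks <- stick_pattern(sys$couplings)

  # all line positions: n_orientations x n_lines
  pos <- vapply(sticks$offset_mhz,
                function(a) centers + mhz_to_mT(a, g_eff),
                numeric(length(g_eff)))
  pos <- matrix(pos, nrow = cfg$n_orientations)
  wts <- matrix(rep(sticks$weight, each = cfg$n_orientations),
                nrow = cfg$n_orientations)

  sigma <- cfg$linewidth_pp / 2
  rng <- cfg$field_range
  if (is.null(rng)) rng <- c(min(pos) - 5 * cfg$linewidth_pp,
                             max(pos) + 5 * cfg$linewidth_pp)
  field <- seq(rng[1], rng[2], length.out = cfg$n_points)
  h <- field[2] - field[1]

  shape <- function(x) {
    if (cfg$lineshape == "gaussian") {
      exp(-x^2 / (2 * sigma^2))
    } else {
      sigma^2 / (x^2 + sigma^2)  # sigma as half-width at half-maximum
    }
  }

  # merge degenerate stick positions (all orientations coincide in the
  # isotropic limit)
  pos_v <- as.vector(pos); w_v <- as.vector(wts)
  key <- round(pos_v * 1e8)  # merge positions within 1e-8 mT (fp jitter scale)
  agg_w <- tapply(w_v, key, sum)
  agg_p <- tapply(pos_v, key, mean)
  ord <- order(agg_p)
  upos <- as.numeric(agg_p[ord]); uw <- as.numeric(agg_w[ord])

  if (length(upos) <= 4096L) {
    # few distinct lines: evaluate the lineshape exactly at each position
    intensity <- numeric(cfg$n_points)
    for (k in seq_along(upos)) {
      intensity <- intensity + uw[k] * shape(field - upos[k])
    }
  } else {
    # dense powder: bin sticks onto the grid (linear split between flanking
    # points keeps the first moment exact), then convolve with the kernel
    idx <- (upos - rng[1]) / h
    keep <- idx >= 0 & idx <= cfg$n_points - 1
    idx <- idx[keep]; w <- uw[keep]
    lo <- floor(idx)
    frac <- idx - lo
    hist <- numeric(cfg$n_points)
    acc_lo <- tapply(w * (1 - frac), lo, sum)
    hist[as.integer(names(acc_lo)) + 1L] <- hist[as.integer(names(acc_lo)) + 1L] + acc_lo
    hi_ok <- frac > 0
    if (any(hi_ok)) {
      acc_hi <- tapply((w * frac)[hi_ok], lo[hi_ok] + 1, sum)
      hist[as.integer(names(acc_hi)) + 1L] <- hist[as.integer(names(acc_hi)) + 1L] + acc_hi
    }
    kernel <- shape(seq(-6 * sigma, 6 * sigma, by = h))
    kernel <- kernel / sum(kernel)
    intensity <- direct_convolve(hist, kernel)
  }

  if (normalize) {
    area <- trapz(field, intensity)
    if (area > 0) intensity <- intensity / area
  }
  epr_spectrum(field, intensity, mode = "absorption")
}

# centered open convolution, same length as x
direct_convolve <- function(x, kernel) {
  full <- convolve(x, rev(kernel), type = "open")
  start <- (length(kernel) - 1L) %/% 2L + 1L
  full[start:(start + length(x) - 1L)]
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' First-derivative spectrum
#'
#' Numerical derivative with respect to field (central differences), the CW
#' detection convention.
#'
#' @param spectrum An absorption-mode `epr_spectrum`.
#' @return An `epr_spectrum` in `first_derivative` mode.
#' @export
derivative_spectrum <- function(spectrum) {
  if (spectrum_mode(spectrum) != "absorption") {
    abort("`derivative_spectrum()` needs an absorption-mode spectrum")
  }
  f <- spectrum$field; y <- spectrum$intensity
  n <- length(y)
  dy <- numeric(n)
  dy[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (f[3:n] - f[1:(n - 2)])
  dy[1] <- (y[2] - y[1]) / (f[2] - f[1])
  dy[n] <- (y[n] - y[n - 1]) / (f[n] - f[n - 1])
  epr_spectrum(f, dy, mode = "first_derivative")
}

#' Double integral of a first-derivative spectrum
#'
#' Spin quantitation primitive: integrates the derivative trace twice by the
#' trapezoid rule. A straight line through the mean of the first and last 2%
#' of points is subtracted from the derivative trace, and again from the
#' running integral, before each integration — the standard CW baseline
#' workup.
#'
#' @param spectrum A `first_derivative` `epr_spectrum` with >= 8 points.
#' @param baseline_frac Fraction of points at each end defining the baseline.
#' @return The double integral (proportional to the number of spins).
#' @export
double_integral <- function(spectrum, baseline_frac = 0.02) {
  if (spectrum_mode(spectrum) != "first_derivative") {
    abort("`double_integral()` needs a first-derivative spectrum")
  }
  n <- nrow(spectrum)
  if (n < 8L) abort("spectrum must have at least 8 points")
  f <- spectrum$field
  y <- endpoint_baseline(f, spectrum$intensity, baseline_frac)
  absorb <- cumtrapz(f, y)
  absorb <- endpoint_baseline(f, absorb, baseline_frac)
  trapz(f, absorb)
}

endpoint_baseline <- function(x, y, frac) {
  n <- length(y)
  k <- max(2L, ceiling(frac * n))
  x1 <- mean(x[1:k]); y1 <- mean(y[1:k])
  x2 <- mean(x[(n - k + 1):n]); y2 <- mean(y[(n - k + 1):n])
  slope <- (y2 - y1) / (x2 - x1)
  y - (y1 + slope * (x - x1))
}

cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (head(y, -1) + tail(y, -1)) / 2))
}

#' Spin fraction of a sample against a quantitation standard
#'
#' Ratio of the sample's double integral to the standard's, scaled by the
#' standard's known spin count and the sample's site count. Double integrals
#' equal absorption areas and are field-grid independent, so the two spectra
#' may live on different grids.
#'
#' @param sample,standard First-derivative `epr_spectrum` objects.
#' @param standard_spins Spins represented by the standard (arbitrary units).
#' @param sample_sites Radical-capable sites in the sample (same units).
#' @return Estimated fraction of occupied sites.
#' @export
spin_fraction <- function(sample, standard, standard_spins = 1, sample_sites = 1) {
  di_std <- double_integral(standard)
  if (di_std <= 0) abort("standard double integral must be positive")
  di_sample <- double_integral(sample)
  (di_sample / di_std) * standard_spins / sample_sites
}

#' Plot an EPR spectrum
#'
#' @param object An `epr_spectrum`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epr_spectrum <- function(object, ...) {
  ggplot2::ggplot(tibble(field = object$field, intensity = object$intensity),
                  ggplot2::aes(x = .data$field, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Magnetic field (mT)",
      y = if (spectrum_mode(object) == "absorption") "Absorption (a.u.)" else "dA/dB (a.u.)"
    ) +
    ggplot2::theme_minimal()
}
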