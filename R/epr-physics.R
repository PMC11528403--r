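# EPR plumbing: the electron-Zeeman resonance condition and first-order
# isotropic hyperfine structure. Field-swept CW spectra put everything in
# magnetic-field units (mT); hyperfine couplings are quoted in MHz and
# converted at the local effective g.

PLANCK_H <- 6.62607015e-34      # J s (exact, SI)
BOHR_MAGNETON <- 9.2740100783e-24  # J/T (CODATA 2018)

#' Resonance field of a g-value
#'
#' Centre field of an S = 1/2 resonance, `B = h nu / (g muB)`, in mT.
#'
#' @param g Effective g-value(s), positive.
#' @param mw_ghz Microwave frequency in GHz (X-band ~9.4, Q-band ~34).
#' @return Field(s) in mT.
#' @examples
#' resonance_field(2.0023, 9.373) # ~334.5 mT
#' @export
resonance_field <- function(g, mw_ghz) {
  if (any(g <= 0)) abort("`g` must be positive")
  if (any(mw_ghz <= 0)) abort("`mw_ghz` must be positive")
  PLANCK_H * mw_ghz * 1e9 / (g * BOHR_MAGNETON) * 1e3
}

#' Convert an isotropic hyperfine coupling from MHz to mT
#'
#' First-order field-swept conversion `a h / (g muB)`.
#'
#' @param a_mhz Coupling(s) in MHz.
#' @param g g-value at which the line appears.
#' @return Splitting in mT.
#' @examples
#' mhz_to_mT(39, 2.0038) # ~1.39 mT, the glycyl doublet splitting
#' @export
mhz_to_mT <- function(a_mhz, g) {
  if (any(g <= 0)) abort("`g` must be positive")
  a_mhz * 1e6 * PLANCK_H / (g * BOHR_MAGNETON) * 1e3
}

#' Hyperfine stick pattern for isotropic couplings to spin-1/2 nuclei
#'
#' Enumerates the first-order line positions `sum_i m_i a_i` over all nuclear
#' spin configurations (`m = +-1/2` per proton), merging equivalent nuclei
#' into binomially weighted lines: one proton gives the glycyl doublet, three
#' equivalent methyl protons the alanyl 1:3:3:1 quartet, and two inequivalent
#' protons with a 2:1 coupling ratio the serinyl 1:1:1:1 four-line pattern.
#'
#' @param couplings List of couplings, each a list with `a_iso` (MHz) and `n`
#'   (number of equivalent spin-1/2 nuclei); may be empty.
#' @param merge_tol Offsets closer than this (MHz) merge into one line.
#' @return Tibble with columns `offset_mhz` (sorted ascending) and `weight`
#'   (normalised so the smallest weight is 1).
#' @examples
#' stick_pattern(list(list(a_iso = 60, n = 3))) # 1:3:3:1 quartet
#' @export
stick_pattern <- function(couplings = list(), merge_tol = 1e-9) {
  offsets <- 0
  weights <- 1
  for (cp in couplings) {
    a <- cp$a_iso
    n <- as.integer(cp$n)
    if (is.null(a) || !is.finite(a)) abort("each coupling needs a finite `a_iso`")
    if (is.null(n) || n < 1L) abort("each coupling needs `n` >= 1")
    # n equivalent spin-1/2 nuclei: total projection M = -n/2 .. n/2,
    # multiplicity choose(n, k)
    m <- seq(-n / 2, n / 2, by = 1)
    w <- choose(n, 0:n)
    offsets <- as.vector(outer(offsets, m * a, `+`))
    weights <- as.vector(outer(weights, w, `*`))
  }
  ord <- order(offsets)
  offsets <- offsets[ord]; weights <- weights[ord]
  # merge degenerate offsets
  grp <- cumsum(c(TRUE, diff(offsets) > merge_tol))
  out <- tibble(
    offset_mhz = as.vector(tapply(offsets, grp, mean)),
    weight = as.vector(tapply(weights, grp, sum))
  )
  out$weight <- out$weight / min(out$weight)
  out
}

#' Diagnose the radical centre from its g-tensor
#'
#' Carbon-centred 2p-pi radicals show near-free-electron g with minimal
#' anisotropy; oxygen-centred radicals show a strongly shifted g-parallel
#' (~2.036). Thresholds are configurable.
#'
#' @param g Numeric length-3 g-tensor principal values.
#' @param carbon_max Maximum g and anisotropy bound for a carbon call.
#' @param carbon_aniso Maximum `max(g) - min(g)` for a carbon call.
#' @param oxygen_min Minimum `max(g)` for an oxygen call.
#' @return `"carbon_centered"`, `"oxygen_centered"` or `"indeterminate"`.
#' @examples
#' radical_center_diagnosis(c(2.004, 2.002, 2.002))
#' radical_center_diagnosis(c(2.036, 2.005, 2.005))
#' @export
radical_center_diagnosis <- function(g, carbon_max = 2.01, carbon_aniso = 0.01,
                                     oxygen_min = 2.02) {
  if (length(g) != 3L || any(!is.finite(g))) abort("`g` must be a finite length-3 vector")
  if (max(g) < carbon_max && (max(g) - min(g)) < carbon_aniso) return("carbon_centered")
  if (max(g) > oxygen_min) return("oxygen_centered")
  "indeterminate"
}
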