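---
title: "Methods: mining and validating aminoacyl radical enzymes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining and validating aminoacyl radical enzymes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aaremine)
```

## The scientific problem

Glycyl radical enzymes (GREs) carry a stable glycine α-carbon radical,
installed post-translationally by a partner radical-SAM activating enzyme
(AE), and use a nearby cysteine thiyl radical for catalysis. The GRE
sequence signature is a C-terminal catalytic-loop fingerprint,
R-V-x-**G**-[FWY], housing the radical glycine, together with a conserved
Cys near the middle of the chain. `aaremine` implements the computational
core of the case that this superfamily also contains *aminoacyl* radical
enzymes (AAREs) — homologs in which the catalytic Gly is replaced by Ala
(ARE), Ser (SRE) or Thr (TRE) — and provides every tool needed to exercise
that case end to end on synthetic data:

1. fingerprint-motif mining with catalytic-residue classification and
   supporting-evidence rules (`screen_proteins()`),
2. genetic-code codon-graph analysis of how the substitutions arise
   (`min_aa_codon_distance()`, `mutational_paths()`),
3. CW EPR powder simulation and spin quantitation of the resulting protein
   radicals (`powder_spectrum()`, `spin_fraction()`),
4. distance-based phylogenetics with bootstrap monophyly tests
   (`bootstrap_support()`, `is_monophyletic()`),
5. seeded generators for all inputs (`generate_family()`,
   `generate_neighborhoods()`, `generate_spectrum()`).

## Candidate classification model

A protein is called GRE/ARE/SRE/TRE only when three independent lines of
evidence coincide:

* a fingerprint hit — the anchored pattern R-V-x-[GAST]-[FWY], scanned
  position by position; the residue in the catalytic slot fixes the class.
  By default the driving hit must lie in the final 25% of the sequence,
  because the catalytic loop is C-terminal in this fold. When hits overlap,
  the most C-terminal one is used.
* a catalytic Cys — at least one cysteine whose relative position falls in
  [0.35, 0.70) of the chain. The window is deliberately generous: the thiyl
  Cys sits near the middle of the barrel but its exact relative position
  drifts with length.
* an adjacent activase — a gene within 500 bp (intergenic, 1-based closed
  GFF3 coordinates: `start(next) − end(prev) − 1`) whose product carries
  the CX3CX2C [Fe4S4]-binding motif of radical-SAM enzymes. Adjacency is
  strand-agnostic by default because real neighborhoods mix orientations;
  `require_coorientation = TRUE` tightens this. An AE claimed by two
  candidates is flagged `two_candidates_one_ae`, the atypical arrangement
  seen for TRE pairs.

Anything with a fingerprint but incomplete evidence is reported as
`fingerprint_only`, never silently dropped.

The fingerprint scan is an anchored position-pattern match, not a
profile/MSA method: the motif is short, strongly anchored, and the
anchors are configurable (`fingerprint_config()`), so a pattern scan
captures it without pulling in an alignment engine. Loosening (e.g.
R→[RK]) is a config change, not a code change.

## Codon-graph analysis

The 64 codons form a graph whose edges connect codons differing at one
nucleotide. `min_aa_codon_distance()` minimises Hamming distance over all
codon pairs of two amino acids; `mutational_paths()` enumerates every
shortest path, annotating the amino acids encoded en route. This
reproduces the key genetic argument for AARE authenticity: Gly→Ala and
Gly→Ser are single point mutations (the Ser route exists from exactly two
Gly codons, via a first-position G→A), whereas Gly→Thr requires two
sequential changes, passing through Ala-, Ser- (or Arg-) encoding
intermediates. The Arg intermediates (AGA/AGG on GGA/GGG routes) are
reported like any other; their biological plausibility is left to the
user.

One caveat worth stating: a minimum over codon *sets* is not a metric.
Symmetry holds, but the triangle inequality can fail (Phe→Gln is 3
substitutions directly, yet 2 via Leu, because the two legs are free to
use different Leu codons). The tests pin this down with a brute-force
64×64 oracle rather than asserting metric axioms that do not hold.

T and U are interchangeable on input and canonicalised to T internally.
Stop codons are excluded from the path graph by default (`allow_stops`
re-admits them as interior nodes); when the shortest stop-free path is
longer than the raw codon distance, the enumeration steps up to
`max_steps` before giving up.

## CW EPR simulation

Radicals are modelled as S = 1/2 with a rhombic g-tensor and isotropic
¹H hyperfine couplings, the level of theory at which all the printed
simulation parameters live. First-order positions are
`B(θ,φ) = hν/(g_eff μB) + Σ m_i a_i·h/(g_eff μB)`, with
`g_eff = sqrt(Σ g_i² l_i²)` over direction cosines `l`. Anisotropic
hyperfine — invoked only qualitatively to rule out β-carbon radicals —
is out of the simulation path.

* **Powder averaging** uses a deterministic golden-spiral point set
  (default 10,000 orientations, uniform weights): reproducible without
  quadrature tables, and convergent — doubling the grid moves the
  normalised spectrum by < 10⁻³ relative L2 at the default.
* **Lineshape** is Gaussian by default with a peak-to-peak width of
  0.6 mT (the derivative peak-to-peak of a Gaussian is 2σ). The width is
  a free parameter: all pattern-level claims (line counts, intensity
  ratios, splittings) are width-robust, and no published linewidth table
  is bundled.
* **Field axis**: 1024 points, auto-ranged to cover every resonance ± 5
  linewidths.
* **Numerics**: degenerate stick positions are merged first; when few
  distinct lines remain (isotropic or axial cases) each line's shape is
  evaluated exactly, which is why the isotropic-g limit matches a direct
  stick convolution to machine precision; dense powders are binned onto
  the grid with a linear two-point split (first moment preserved) and
  convolved with the sampled kernel.

The diagnostic patterns fall straight out of `stick_pattern()`: one
proton at 39 MHz gives the glycyl doublet; three equivalent methyl
protons at ~60 MHz give the alanyl 1:3:3:1 quartet (binomial weights,
verified against explicit 2ⁿ enumeration); protons at 60 and 30 MHz give
the serinyl 1:1:1:1 four-line pattern; the threonyl system has no
resolved splitting and is diagnosed instead by its g-tensor
(`radical_center_diagnosis()`: carbon-centred below g = 2.01 with
anisotropy < 0.01; oxygen-centred above 2.02).

## Spin quantitation

`double_integral()` integrates a first-derivative trace twice by the
trapezoid rule. A straight line through the means of the first and last
2% of points is subtracted from the derivative *and again from the
running integral* before the second integration. The second correction
matters: integrated white noise is a random walk, and its drift —
not the point-wise noise — dominates the error of an uncorrected double
integral. With it, planted fractions of 0.045–0.28 are recovered within
±0.02 at SNR 50 on the default 1024-point axis.

Because a double integral equals the absorption area, it is independent
of the field grid; `spin_fraction()` therefore integrates sample and
standard each on its own grid rather than resampling. The synthetic
standard is a noiseless single line normalised to unit absorption area
representing one spin per site, so the estimator reduces to the sample's
double integral scaled by `standard_spins / sample_sites`.

## Phylogenetics

Maximum-likelihood inference is deliberately replaced by neighbor
joining on Poisson-corrected p-distances (`−ln(1−p)`, p over ungapped
site pairs) with column bootstrap — a desk-scale, dependency-free
substitute sufficient to test the structural claim at stake: that each
AARE class forms its own clade. The NJ implementation is in-package so
its behaviour is fully specified: Q-criterion ties break toward the
lowest index pair, and negative branch-length estimates are clamped to
zero with the total deficit recorded and warned about. `ape` supplies
the tree container, rooting and the independent NJ cross-check in the
tests (on random additive matrices both implementations must recover
the generating topology exactly).

Bootstrap supports are fractions of replicates containing each internal
bipartition of the full-data tree, with splits canonicalised by the side
away from the lexicographically smallest tip. Monophyly is tested on the
tree rooted at an explicit outgroup leaf (an NrdD-like distant GRE in the
synthetic families).

## What the synthetic data emulate — and what they do not

`generate_family()` produces the study conditions under which the
pipeline's claims are tested: 17 AREs, 21 SREs and 71 TREs by default
(the discovery-scale class counts, 109 AAREs in total), protein length
800, one class ancestor per class diverging from a common ancestor at
0.12 substitutions per site, leaves diverging from their class ancestor
at a third of that, plus Cys-free decoys, decoys destined to lack an AE
neighbor, and one distant outgroup at threefold divergence. Those rates
were chosen once to give within-class identities in the 40–50% band
with clearly separated classes, the regime the real family occupies.
Random residues are drawn from a Cys-free alphabet so the planted
catalytic Cys is the unique thiol; motif anchors and the Cys are frozen
during descent; substitutions are uniform over amino acids (no
empirical exchange matrix — nothing downstream depends on realistic
exchangeabilities). Reverse translation is deterministic, and the
planted catalytic codon follows the minimal mutational path from GGT
(GCT, AGT, ACT), so the emitted CDS encodes the same genetic logic the
codon module analyses.

Because the generator mutates sites independently and never gaps them,
the sequences are site-homologous by construction — synthetic "alignments"
are exact, and miner precision/recall of 1.0 is a round-trip property of
the planted evidence rules, not a statement about real, indel-riddled,
convergently mutated databases. Likewise the monophyly result shows the
NJ+bootstrap machinery recovers planted clade structure; it cannot stand
in for the ML analysis of the real superfamily. Real-data caveats that
the generator does not emulate: alignment error, compositional bias,
fingerprint variants outside the configured anchor sets, and activase
genes beyond the 500 bp gap rule.

`generate_spectrum()` scales a simulated powder spectrum by a known
fraction and adds Gaussian noise at a stated SNR (sd = peak/SNR on the
derivative trace); it does not emulate baseline drift, microwave-phase
error or saturation, which is why quantitation accuracy on it is a
parameter-recovery statement, not a reproduction of the experimental
numbers.

## Problem sizes and determinism

Demonstration and test runs use the default family (120 sequences of
length 800: 109 AAREs, 10 decoys, one outgroup), 100 bootstrap replicates, 10,000-orientation powder grids
and 1024-point spectra; unit tests use scaled-down counterparts
(10-sequence families, 500-orientation grids) chosen as the smallest
sizes at which each property is already stable. Every stochastic stage
takes an explicit integer seed, and each generator seeds its own stream,
so family, neighborhoods, bootstrap and noise are independently
reproducible; identical seeds give byte-identical outputs.

## Worked example

```{r example, eval = FALSE}
fam <- generate_family(family_spec())
nb  <- generate_neighborhoods(fam)
scr <- screen_proteins(family_protein_db(fam, nb), genes = nb$genes)
glance(scr)
screen_performance(scr, fam$truth)

mutational_paths("G", "T", max_steps = 2)

quartet <- stick_pattern(list(list(a_iso = 60, n = 3)))
gen <- generate_spectrum(radical_spin_system("alanyl"), planted_fraction = 0.045)
spin_fraction(gen$sample, gen$standard)
```

## Known limitations

* The fingerprint scan cannot find family members whose catalytic loop
  diverges from the configured anchors; it is a detector for the printed
  motif, not a remote-homology search.
* Hyperfine treatment is first-order and isotropic; strongly anisotropic
  couplings or higher-order effects (visible at Q-band for some systems)
  are outside the model.
* NJ is statistically inconsistent in regimes (long-branch attraction)
  where ML is not; conclusions about deep topology should not rest on it.
* Dereplication of redundant sequences and database retrieval are out of
  scope; inputs are assumed non-redundant.
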