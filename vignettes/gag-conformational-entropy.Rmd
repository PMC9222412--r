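---
title: "Conformational entropy of GAG chains: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational entropy of GAG chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gagentropy)
```

## The model

A linear glycosaminoglycan of M NG disaccharide repeats (N = GlcNAc for
hyaluronan, GalNAc for chondroitin-6-sulfate; G = GlcA) exposes two torsion
angles per glycosidic linkage. Writing O1 for the bridging glycosidic oxygen
of the donor unit, the 1→4 linkage (N donating to G) is described by

$$\Phi_{1\text{-}4} = \mathrm{O5(N)-C1(N)-O1(N)-C4(G)}, \qquad
  \Psi_{1\text{-}4} = \mathrm{C1(N)-O1(N)-C4(G)-C5(G)},$$

and the 1→3 linkage (G donating to N) by

$$\Phi_{1\text{-}3} = \mathrm{O5(G)-C1(G)-O1(G)-C3(N)}, \qquad
  \Psi_{1\text{-}3} = \mathrm{C1(G)-O1(G)-C3(N)-C4(N)}.$$

With the NG-start convention (the chain begins with an N unit and ends with a
G unit) an M-repeat chain has M 1→4 and M−1 1→3 angle pairs; M = 24 gives the
24/23 counts used throughout. The reducing/non-reducing orientation of the
termini is a convention here, not an inference: only linkage-interior atoms
enter any computed quantity, so the choice affects labels, not numbers.

For each angle-pair type, the (Φ, Ψ) values of **all** linkages and **all**
frames are pooled into one bivariate histogram on (−180°, 180°]² and the
conformational entropy is the scaled Shannon entropy of its bin probabilities
$p_{ij}$:

$$S = -R_0 \sum_{i,j} p_{ij}\,\ln p_{ij}, \qquad R_0 = 8.314\;\mathrm{J\,K^{-1}\,mol^{-1}}.$$

Pooling linkages treats the chain's conformational ensemble as stationary
along the chain; the entropy is a static property of the occupancy map and is
exactly invariant to frame order and to any permutation of bins.

## Estimators and numerical choices

- **Logarithm base.** Natural log: pairing with the gas constant follows the
  thermodynamic convention S = −R Σ p ln p, and makes the uniform-distribution
  ceiling R₀·ln B.
- **Binning.** Default 72 bins per axis (5° bins), half-open intervals
  (low, high] so that +180° lands in the last bin — matching the dihedral
  branch convention below. B = 72² gives a ceiling of
  R₀·ln 5184 ≈ 71.1 J·K⁻¹·mol⁻¹, comfortably above the 50–65 J·K⁻¹·mol⁻¹ band
  where flexible protein-bound GAG chains typically land, while 5° is close to
  the resolution at which modal conformations are usually quoted. Binned
  entropy depends on the bin width, so `bins_per_axis` is carried in every
  `entropy_record` and must match when comparing values.
- **Estimator.** Plug-in (maximum-likelihood) by default, computed directly
  from the empirical frequencies. It is biased low by ≈ R₀(m−1)/(2n) for m
  occupied bins; at the study scale (n = 24 000, m of order 10³) that is a few
  tenths of a J·K⁻¹·mol⁻¹. `miller_madow = TRUE` applies exactly that
  first-order correction; it is off by default because the plain frequency
  computation is the reference definition, and comparisons between conditions
  share the bias.
- **Dihedral convention.** IUPAC sign (positive = clockwise rotation of the
  far bond viewed from the second to the third atom), range (−180°, 180°] with
  +180° (not −180°) as the planar-trans branch, computed by the atan2 form
  which is stable near collinearity; genuinely degenerate quadruples
  (coincident or collinear reference points, tolerance 1e−10 on normalized
  cross products) raise a geometry error rather than returning noise.
- **Modes.** `most_frequent_angles` returns the center of the maximal-count
  bin (modes are necessarily discretized to the bin width); exact count ties
  are broken by the lexicographically smallest (Φ, Ψ) center so results are
  deterministic.
- **Degenerate inputs.** Empty series, empty histograms and degenerate regions
  are errors, not NaNs; a 1-repeat chain legitimately has an empty 1→3 series
  (frames × 0 matrix), which extraction returns but histogramming refuses.

## The synthetic generator

`sample_angle_series` draws (Φ, Ψ) pairs from a mixture of angular clusters
plus a uniform background. Each cluster is an independent von Mises
distribution per axis (Best–Fisher rejection sampling; κ = 0 is uniform,
κ = ∞ the zero-dispersion point mass), so clusters are compact blobs like the
basins seen in glycosidic occupancy maps; correlated (tilted) components are
deliberately not the default. Frames are i.i.d. by default. An optional sticky
component-switching mode (`ar1`) adds temporal correlation while leaving the
marginal mixture — and therefore the pooled-histogram entropy — unchanged;
it only slows Monte-Carlo convergence, which is why it is off by default.

The default study conditions mirror a protein-bound GAG setting:

- chains of 24 NG repeats sampled for 1000 frames (the saved-state pattern of
  a 100 ns run stored every 100 ps); these are generator defaults and
  validation warnings for real inputs, not hard requirements, since nothing in
  the entropy depends on frame count beyond sampling error;
- cluster centers per GAG and angle-pair type at the modal conformations and
  secondary basins reported for HSA-bound HA and CS6 (e.g. the dominant CS6
  1→4 conformer near (−72°, −76°), HA 1→4 helix basins near (−72°, −126°) and
  (−97°, −155°));
- a base concentration κ = 3 on the dominant basin and a 10% uniform
  background, chosen once so that pooled-histogram entropies land in the
  realistic 55–65 J·K⁻¹·mol⁻¹ band for a flexible bound chain;
- ion labels mapped to a κ multiplier (Na⁺ 1.25, Mg²⁺ 1.0, Ca²⁺ 0.8),
  encoding as a *generative condition* the observed ordering that Na⁺ systems
  are the most conformationally ordered and Ca²⁺ the least. N = 10
  realizations per (GAG, ion) group, summarized by median/min/max — with
  N = 10 the extremes roughly estimate the 10th and 90th percentiles.

What passing tests on this generator do and do not show: they verify the
estimator and pipeline against known ground truth (mixture weights, modes,
closed-form entropies), but synthetic clusters are stationary, uncorrelated
across axes and free of the slow conformational drift, solvent memory and
ion-specific contact chemistry of real MD data. Agreement on synthetic data
therefore validates the *arithmetic*, not any physical claim about a specific
system; absolute entropies from real trajectories additionally depend on the
chosen binning, which must be reported alongside S.

## Torsion embedding as ground truth

`embed_torsions_as_coordinates` converts a prescribed angle series into 3D
coordinates by sequential internal-coordinate (NeRF) construction with unit
bond lengths and tetrahedral (109.5°) bond angles: each linkage's Φ places the
acceptor's first ring atom and Ψ the second, while the remaining atoms are
scaffolded at fixed torsions. The geometry is *not* a physical sugar — only
the glycosidic dihedrals are meaningful — but extraction from the embedded
coordinates reproduces the prescribed angles to < 1e−6°, which makes the
extraction path testable end-to-end, including through multi-model PDB
write/read (where fidelity drops to the 0.1° implied by the fixed 3-decimal
PDB coordinate field). Periodic-boundary unwrapping is not attempted:
trajectories are assumed whole-molecule, as saved states from MD engines and
embedded frames both are.

## Design choices that were genuinely open

- **Atom naming.** One canonical scheme (O5/C1/O1/C3/C4/C5); other PDB
  dialects are translated via a user alias map rather than guessed.
- **Pooling vs per-linkage entropy.** Entropies are computed per angle-pair
  type from the pooled histogram, and realizations are never pooled with each
  other — summaries are order statistics over per-realization values.
- **Problem sizes in tests.** Property suites run at reduced sizes (e.g.
  50–200 frames, 20 replicate studies for the spread-ordering check) chosen so
  the statistical assertions retain power; the acceptance script runs the full
  2 GAGs × 3 ions × 10 realizations × 1000 frames study, which completes in
  seconds because sampling and histogramming are vectorized.

## Known limitations

- Linear chains only; branched glycans and trajectory
  alignment/superposition are out of scope.
- The entropy is the binned plug-in estimate (optionally Miller–Madow); no
  kernel density or continuous differential entropy.
- Ion labels are grouping metadata everywhere; ions are never modeled as
  particles, and the generator's ion effect is a prescribed spread multiplier,
  not chemistry.
- Absolute S values are bin-width dependent; cross-study comparisons require
  identical binning.

## A minimal run

```{r example, eval = FALSE}
top <- build_chain("CS6", 24)
series <- simulate_realization("CS6", "Na+", realization_id = 1, seed = 101)
res <- run_realization(series, config = list(ion = "Na+", realization_id = 1))
res

st <- run_study(seed = 1)   # full synthetic study
st$summary
```
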