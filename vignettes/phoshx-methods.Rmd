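---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the statistical models, conventions and numerical
choices behind each `phoshx` module, what the synthetic-data generators do
and do not emulate, and the design decisions taken where the underlying
methodology was genuinely open. It states no empirical result that the test
suite does not itself compute.

## Hotspot scoring

A phosphosite's observation frequency is the sum of two curated counts:
published mass-spectrometry studies (`MS_LIT`) and unpublished curated MS
experiments (`MS_CST`). Its characterization ratio is
`(LT_LIT + 1) / (MS_CST + MS_LIT)`, where `LT_LIT` counts low-throughput,
experimentally validated reports. The `+1` pseudocount is applied to the
numerator only — without it, the large majority of sites (which have no
low-throughput characterization at all) would collapse to an
uninformative 0. The ratio is undefined (an error, not `NA`) when a site
has zero MS observations.

Ranking is by frequency descending. Ties are broken by accession then
position, both ascending — an arbitrary but deterministic rule, required so
that repeated runs and the brute-force sort oracle agree exactly. The "top
fraction" is the first `ceiling(fraction × N)` entries; with the ceiling
convention a 1% cut of 239,530 sites gives 2,396, slightly below the round
2,400 a hand analysis might quote, which is documented here as a convention
rather than a discrepancy.

## Differential phosphosite analysis

Input is a site-by-sample matrix of log-scale abundances with a two-group
design (`altered` vs `wildtype`). Per site:

* **Test.** Two-sided Wilcoxon rank-sum. The exact null distribution is
  used when the pooled non-missing sample size is at most 25 and there are
  no ties; otherwise the normal approximation with tie-corrected variance
  (and no continuity correction) is used. The switch point is a convention;
  the exact branch is validated against full enumeration of all group-label
  assignments for every `n1, n2 ≤ 6`.
* **Effect size.** Log fold change = median(altered) − median(wildtype) on
  the provided log scale. The median was chosen over the mean for
  robustness to the heavy-tailed outliers typical of tumor
  phosphoproteomes; with symmetric noise the two coincide in expectation.
* **Multiplicity.** Benjamini–Hochberg across *tested* sites only. Sites
  with fewer than `min_per_group` (default 3) non-missing values in either
  group are excluded from the family and flagged `tested = FALSE` rather
  than given a fabricated p-value: including never-testable sites would
  only dilute the BH family.

A consequence worth knowing: the exact test has a p-value floor of
`2 / choose(n1 + n2, n1)` (≈ 1.55 × 10⁻⁴ at 8 vs 8). BH significance of a
single strong site at FDR 0.05 is therefore *impossible* in families larger
than ~320 sites at that sample size, no matter how large the effect. In
genome-scale families the meaningful statement is rank-based (the planted
site attains the smallest q), which is what the test suite asserts for a
200-site family; calibrated power statements are made on small targeted
panels.

## HX-MS pseudo-residue uptake

**Exchangeable residues.** A peptide of length L has `L − 2 − #P`
exchangeable backbone amides, where `#P` counts prolines at positions ≥ 3:
the N-terminal amine plus the fast-exchanging second amide are not counted
(the common two-residue convention; one-residue variants exist, and the
choice only rescales the theoretical maximum), and proline has no amide
hydrogen.

**Back-exchange correction.** Uptake is expressed as a fraction of maximum
labeling. When fully deuterated controls exist for a peptide, the maximum
is the mean over *all* replicates and *all* variants of (full-D centroid −
that variant's mean undeuterated centroid) — pooling is deliberate, since
back-exchange is a property of the peptide and workup, not of the variant.
Without controls the theoretical maximum
`N_exch × d2o_fraction × 1.00628 Da` is used. Because measured and maximal
uptake lose deuterium through the same workup, any common retention factor
cancels; this invariance is asserted by test. Fractions are not clamped:
values slightly outside [0, 1] are real features of noisy centroids and are
reported with a flag.

**Residue-level averaging.** A peptide informs residues `start+2 .. end`
(mirroring the exchangeable-residue convention). Per residue and timepoint,
uptake fractions of all covering peptides are averaged within each variant;
the per-timepoint differences (variant − reference, percentage points) are
then averaged with equal weights. The sign convention makes a destabilized,
more-exchanging variant positive. Prolines stay in the coverage map — they
carry information only through the peptide average, a documented limitation
of pseudo-residue maps. No significance testing is attached to d̄D; the
maps are descriptive, as is standard at typical HX-MS replicate counts.

**Filters.** The shipped defaults mirror published assignment-filter
settings (length 3–15, charge ≤ 3, 30/7 ppm, 0.020 Da MS/MS, score 0.05,
0.1 D/e and 0.5 min degeneracy cutoffs). Only length and charge act on an
already-assigned peptide list; the rest document the upstream assignment
stage, which is out of scope.

## Enzymology

* **Initial rates**: OLS slope over the earliest points spanning ≤ 10% of
  the total signal change (≥ 4 points). For an exponential approach
  `A(1 − e^{−kt})` this recovers `A·k` within ~5%.
* **Michaelis–Menten**: `Y = Vmax·X/(Km + X)` by `nls` (port algorithm,
  positivity bounds, tolerance 1e-10, pooled replicate points). Starts:
  `Vmax` = max observed rate, `Km` = concentration nearest half-max.
  `kcat = Vmax/[E]` holds exactly by construction; a boundary-pinned
  parameter is reported as non-convergence, never silently accepted.
* **IC50**: four-parameter logistic
  `y = bottom + (top − bottom)/(1 + (dose/ic50)^hill)` — the log-dose 4PL
  in its dose-scale form, so the fitted response at `dose = ic50` is
  exactly the plateau midpoint. Non-decreasing dose trends and fits whose
  IC50 escapes the dosed range report `converged = FALSE`.
* **Melting temperature**: Tm is the inflection of fluorescence vs
  temperature, located as the argmax of a Savitzky–Golay first derivative
  (local quadratic), refined by quadratic interpolation around the discrete
  peak. The estimate is invariant under affine transforms of the signal. A
  peak must be interior and exceed the median derivative by 3 MADs;
  strictly linear traces therefore fail with "no transition". The default
  window is 41 points (~4 °C on the 0.1 °C instrument ramp): a 9-point
  window was evaluated and recovers Tm to ±0.5 °C in only ~57% of
  replicates at 2% amplitude noise, whereas 41 points achieves ≥ 99% while
  remaining narrow relative to a ~6 °C transition. The window is
  user-configurable.
* **Activation profiles** are endpoint activities relative to the
  zero-peptide baseline (the underlying assay reads fluorescence at a fixed
  time, not a rate). "Could not be activated" is operationalized as maximum
  fold activation < 1.2 — roughly twice a typical 10% assay CV above unity.

All fits are deterministic: fixed initializations, no random restarts.

## Structural superposition

Cα-only Kabsch superposition over residues common to both models, pairing
by (chain, residue number + offset, insertion code); no sequence alignment,
no iterative outlier trimming (published comparisons quote single global
RMSDs). Alternate locations resolve to the highest occupancy, ties to
altloc `A`. Reflections are excluded by the determinant correction, so the
rotation is always proper. Collinear point sets are rejected: the optimal
rotation is not unique there. Optimality is spot-checked against 10,000
random proper rotations and, on a tiny configuration, against a dense
rotation-grid search. Reproduction of published RMSD values for specific
structure pairs would additionally depend on the (unstated) atom selection
and residue range used there; the module makes those choices explicit
arguments instead of guessing.

## Synthetic-data generators

All generators are pure functions of (parameters, seed), restore the
caller's RNG state, and serialize their ground truth as JSON beside any
files written.

* **Site tables** use geometric background counts (long-tailed, like the
  real frequency distribution), sparse `LT_LIT`, S/T/Y drawn at
  0.65/0.20/0.15, blank cells for zero counts and a banner before the
  header — enough to exercise the parser's dialect handling. Hotspots are
  planted strictly above the background maximum.
* **Abundance matrices**: Gaussian log-abundances (site baselines ~N(20,2),
  within-group sd 1 by default — the scale of log2 tumor phosphoproteome
  intensities), additive group shifts, missing completely at random at 10%
  by default. Real missingness is partly intensity-dependent; MCAR is a
  documented simplification, so green tests establish correctness of the
  testing machinery, not robustness to informative missingness.
* **HX centroids** follow two-state Linderstrøm-Lang kinetics in the EX2
  limit, `u_i(t) = 1 − e^{−(k_int/PF_i)t}`, with a single configurable
  intrinsic rate (default 1 s⁻¹; full sequence-dependent intrinsic-rate
  tables are out of scope, and a per-residue vector hook is provided).
  Defaults: D2O fraction 0.9 (tenfold dilution into deuterated buffer),
  back-exchange retention 0.85 (typical 10–30% loss), Gaussian centroid
  noise, 2 replicates. No EX1 bimodality, no envelope shapes, no
  retention-time artifacts.
* **Kinetics/inhibition/melt**: exact mean curves plus fractional Gaussian
  noise; the melt sigmoid's inflection is the Tm parameter by construction.
* **Structure pairs**: 3.8 Å random-step Cα traces, a uniform-ish random
  proper rotation (QR-based) plus translation, optional isotropic
  displacements with the closed-form expected RMSD `σ√3`.

## Known limitations

* The PhosphoSitePlus reader targets the tab-separated site-table dialect
  with optional banner; it is not a general curation-database parser.
* Pseudo-residue d̄D inherits peptide-level resolution; single-residue
  claims near coverage boundaries should be read with the coverage count.
* The Wilcoxon power analysis above shows BH-calibrated single-site claims
  are structurally impossible at genome scale with n = 8/8; use ranks.
* The PDB writer emits minimal ATOM/END records (no SEQRES, no elements
  column), sufficient for coordinate round-trips and B-factor painting.
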