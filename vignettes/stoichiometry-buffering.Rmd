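---
title: "Quantifying dosage compensation of complex subunits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dosage compensation of complex subunits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stoichbuffer)
```

## The problem

When the copy number of a yeast gene is driven up — for instance by a
multicopy plasmid under genetic tug-of-war (gTOW) selection, reaching tens
of copies per cell — mRNA output rises roughly in proportion, but for a
subset of genes the protein level does not. These dosage-compensated genes
are almost always subunits of multi-protein complexes, and the buffering is
post-translational: subunits that fail to assemble are ubiquitinated and
degraded. `stoichbuffer` implements the quantitative machinery for such a
study: blot densitometry, gTOW copy-number estimation, screen
classification and statistics, a mechanistic two-pool kinetic model, and a
translational-efficiency stage to exclude the alternative (translational)
mechanism.

## The two-pool heterodimer model

The model tracks free monomers A and B and their heterodimer C under
mass-action kinetics:

$$\frac{dA}{dt} = N_A s_A - d_{f,A} A - k_{on} A B + k_{off} C$$
$$\frac{dB}{dt} = N_B s_B - d_{f,B} B - k_{on} A B + k_{off} C$$
$$\frac{dC}{dt} = k_{on} A B - k_{off} C - d_c C$$

Assumptions worth stating explicitly:

* **Two degradation regimes.** A free monomer decays at $d_f$, a
  complex-bound one at $d_c \le d_f$. The entire compensation phenotype
  flows from this asymmetry; setting $d_f = d_c$ provably removes it
  (the total then obeys a single linear birth–death law, and every
  dosage fold change is exactly 1 — the limit a fully proteasome-defective
  mutant approaches).
* **Synthesis proportional to copy number**, with per-copy rates $s_A$,
  $s_B$. Translation-rate feedback is deliberately absent: the
  ribosome-profiling stage exists to show TE does not change, so the model
  must not assume it does. A synthesis-scaling hook (`s_A`, `s_B`
  themselves) is the only entry point for that alternative.
* **Tag bookkeeping without extra equations.** Tagged and untagged chains
  are kinetically identical, so the tagged share of every pool is
  `tagged_copies_A / N_A`. A denaturing blot measures
  `tagged_total_A = tagged_A_free + tagged_C`; a native gel measures
  `tagged_complex = tagged_C`.
* **Dimer only.** Larger complexes and RNA-containing assemblies are out of
  scope; the dimer already exhibits the full bidirectional phenomenology.

### Parameters, units, defaults

The shipped calibration (`inst/extdata/default_model.yaml`) uses hours as
the time unit and arbitrary concentration units:

| parameter | default | meaning |
|---|---|---|
| `s_A`, `s_B` | 1.5, 1.0 | synthesis per gene copy (AU/h); A in mild excess |
| `d_free_A/B` | 5.0 | free-pool degradation (1/h) |
| `d_complex` | 1.0 | complex degradation (1/h) |
| `k_on` | 100 | association (1/(AU·h)); fast but not diffusion-limit |
| `k_off` | 0 | tight dimer |
| `N_A`, `N_B` | 1 | baseline gene copies; `tagged_copies_A = 1` |

This set was chosen once so that the three perturbation predictions land
inside the experimentally observed windows — 20× self dosage gives a
0.377-fold tagged level (observed compensated range 0.2–0.6 at 15–27
copies), partner deletion gives 0.333 (< 0.5), and 20× partner dosage
gives 1.649 (> 1.3). A 5:1 stability ratio and a modest synthesis excess of
the compensated subunit are the physically meaningful dials; the
predictions are insensitive to `k_on` once association is fast compared
with free-pool turnover.

### Numerical choices

At steady state the net flux into the complex pool is $\kappa A B$ with
$\kappa = k_{on} d_c / (k_{off} + d_c)$, which reduces the balance to a
single quadratic in one free-monomer concentration for *any* $k_{off}$.
The solver therefore uses the closed form throughout (stable root
$B = 2Q / (b + \sqrt{b^2 + 4 a Q})$), verifies residual fluxes to 1e-9
relative, and refuses genuinely ill-posed inputs (complex formed but never
removed; a synthesized monomer with zero degradation). Long ODE integration
(`deSolve`) appears only as an independent oracle in the test suite and in
`simulate_chx()`, where the transient matters. The fast-association limit
has a separate closed form (`flux_limit_fold()`) used as a second,
derivation-independent oracle: at $k_{on} = 10^6$ the general solver agrees
with it to within 2% over a 27-point grid.

`fit_parameters()` estimates the ratios $s_A/s_B$ and $d_f/d_c$ (and
optionally $k_{on}$) by least squares in log-fold space. The landscape is
smooth but can be flat along $k_{on}$; optimization is multi-start over a
fixed grid of log-space starting points (deterministic — no RNG), with a
simplex and quasi-Newton polish for multi-parameter fits. Note that holding
a non-free parameter at a wrong value (e.g. `k_on` far from the generating
one) biases the recovered ratios slightly; that is model mismatch, not an
optimizer failure.

## Measurement stages: conventions and edge cases

**Densitometry.** Background is a per-band value supplied in the table
(image segmentation is upstream); a background exceeding the raw signal is
an error, never clipped. Saturation is an input flag and poisons any fold
computation it touches. The Multi/Single protein fold divides the target's
blot ratio by the loading-control ratio, making it invariant under
per-condition exposure changes (asserted to 1e-12). Zero-variance dilution
series define $R^2 = 0$ and fail the linearity flag. Half-lives come from
ordinary least squares on log level vs time ($t_{1/2} = \ln 2 / |slope|$);
fits with fewer than three time points are refused and non-decaying series
return an undefined half-life rather than a negative one. Replicates
aggregate as arithmetic mean ± sample standard deviation. Per-copy folds
are computed per replicate and then averaged; normalizing after averaging
would give the same point estimate but an inconsistent dispersion.

**Dosage.** Copy number is efficiency-corrected relative quantification of
the plasmid marker against the single-copy genomic locus,
$E_{LEU3}^{Cp_{LEU3}} / E_{leu2d}^{Cp_{leu2d}}$; mRNA folds are ΔΔCp against
ACT1. Default efficiency is 2.0 with a per-primer override column. No
correction is attempted for the plasmid-free population fraction.

**Screen statistics.** No quantitative classification cutoff is standard in
this assay, so the defaults are a protein fold ≤ 0.7 (hits in practice fall
at or below 0.6) and an mRNA band of [0.7, 1.4] encoding "endogenous mRNA
unchanged"; both are arguments, and a protein reduction with an mRNA change
outside the band is reported as *indeterminate*, never as compensation.
The Mann–Whitney test is exact by complete enumeration up to a pooled
n of 12 — covering the n = 3–6 designs where the normal approximation is
worthless — with ties handled by permuting the observed values; beyond
that, the tie-corrected normal approximation takes over. The 2×2 chi-square
is Pearson without continuity correction by default (Yates optional) and
takes raw counts only: the package never fabricates a contingency table on
the user's behalf.

**Ribosome profiling.** Footprints of 26–30 nt map to A-site offsets by the
linear rule `length − 13` (13–17 nt); mRNA fragments of 22–51 nt use a
fixed 15 nt. Whether the underlying offset estimation was empirical per
dataset cannot be settled from a methods description alone, so an explicit
offset table can override the linear map. Counting excludes the first 15
and last 5 codons: A-sites in `[cds_start + 45, cds_end − 15)`. Ribosome
density is footprint count per countable nt; the effective length cancels
in every TE fold (asserted by perturbation), so its exact convention is
immaterial downstream. Size factors are median-of-ratios over genes nonzero
in all samples. Genes with a zero Single-condition count are flagged with
`NA` folds, not dropped and not pseudocounted by default. Differential
testing (negative-binomial shrinkage) is intentionally absent: the claims
this stage supports are fold-change statements.

## What the synthetic generators emulate — and what they do not

Each generator draws from the standard minimal noise model for its assay:
multiplicative lognormal noise for band intensities (plus a shared per-lane
factor that the fold computation must cancel, and a saturation ceiling),
additive Gaussian noise on qPCR crossing points, negative-binomial counts
for sequencing, and lognormal fold distributions for the screen (median 0.4
for compensated genes, 1.0 otherwise, mRNA folds near 1 for both). All
randomness is scoped to the generator's `seed` argument (the caller's RNG
stream is untouched), identical seeds give identical bytes, and every
generator returns its programmed truth for round-trip testing.

They do **not** emulate: spatial gel artifacts or smearing, antibody
affinity differences, PCR inhibitors or melt-curve failures, multimapping
or rRNA contamination in sequencing, batch structure across replicates, or
any correlation between a gene's expression level and its noise. Passing
round-trip tests therefore demonstrates that the estimators are correct
and unbiased under the stated noise models at realistic magnitudes — not
that they are robust to every pathology of real gels and libraries.

Default problem sizes mirror the study design they emulate: 3 blot
replicates, 4 qPCR replicates, a 54-gene screen with 5 compensated genes,
2 profiling replicate pairs at ~500 mean counts over ~30 genes, and chase
sampling at 0, 1, 2, 4, 6 h. The test suite's property checks (flux
balance, exposure invariance, null type-I error at 10,000 simulations) run
at sizes chosen to exercise the mathematics, not the throughput, of each
stage.

## Known limitations

* The kinetic model is deterministic and well-mixed; stochastic effects at
  low copy number (a handful of molecules per cell) are outside its remit.
* Cotranslational assembly and degradation — plausible refinements of the
  two-pool picture — are not modeled; the free pool is a single
  homogeneous species.
* The classifier's thresholds are screen-calibration choices, not
  universal constants; a different tag or detection chemistry may warrant
  different defaults.
* `fit_parameters()` identifies ratios, not absolute rates: fold-change
  observations constrain $s_A/s_B$ and $d_f/d_c$ but carry no time scale.
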