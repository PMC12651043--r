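---
title: "Methods: erythrocyte cytoarchitectonics and hemoglobin ligand-form analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: erythrocyte cytoarchitectonics and hemoglobin ligand-form analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erythrospec)
```

## The measurement problem

Membrane-active drugs redistribute erythrocytes across shape classes:
the normal biconcave discocyte can acquire outgrowths (echinocytes) or
surface ridges — reversible deformations — or progress to dome-shaped
cells, spherocytes, spiked spherocytes, stomatocytes, "deflated ball"
cells and degenerative forms, which are irreversible. In parallel, a
drug that reaches the cell interior can shift intracellular hemoglobin
between its ligand forms (oxy-, deoxy-, methemoglobin) or perturb the
protein's absorption bands. `erythrospec` implements the quantitative
layer for both readouts, plus generators that simulate the raw data the
analysis consumes.

## Shape-class accounting and transformation indices

A donor's SEM counting session yields integer counts over named shape
classes. `aggregate_profile()` converts counts to percentages and sums
them by category using a configurable taxonomy (`shape_taxonomy()`);
`RD + ID = 100` holds exactly for every donor because the two
categories partition the classes. The indices are

$$\mathrm{TI} = \frac{RD + ID}{D},\qquad
  \mathrm{RTI} = \frac{RD}{D},\qquad
  \mathrm{IRTI} = \frac{ID}{D},$$

so that $\mathrm{TI} = \mathrm{RTI} + \mathrm{IRTI}$ identically and
$\mathrm{TI} \ge 1$ whenever $D > 0$. At $D = 0$ the indices are
reported as undefined (a hard error), not as infinity.

Design choices made where the conventions were genuinely open:

* **Stomatocytes sit in the ID category** in the default taxonomy.
  Published category totals for minocycline-treated panels are only
  internally consistent under that assignment, although stomatocytes
  are sometimes listed with the reversible forms elsewhere. The
  taxonomy is data, not code, so the alternative assignment is one
  `shape_taxonomy(extra = ...)` call away.
* **RTI and IRTI as RD/D and ID/D** are inferred conventions: they are
  rarely written out, but they reproduce every published index value we
  calibrate against (all fifteen condition × index cells of the
  reference table, checked in the test suite) and make the TI
  decomposition exact. The pipeline logs this inference once per run.
* **Mean of ratios, not ratio of means.** Profiles and indices are
  computed exactly per donor and averaged afterwards, which is the only
  order compatible with reporting an SEM for an index. Category means
  published as per-row donor averages can therefore differ from sums of
  published class means by ~0.1–0.2 percentage points; the invariant
  `RD + ID = 100` is enforced on per-donor computations only.
* **Reporting rounding** is half-away-from-zero (`round_reported()`):
  1 decimal for percentages, TI and RTI, 2 decimals for IRTI, matching
  how such tables are printed. R's default banker's rounding would
  disagree on half-way cases. The scaled value is snapped to 12
  significant digits before rounding so binary representation error
  cannot flip a half-way case.
* The published "±" values are treated as SEM over the 30-donor panel
  (both sd and SEM are reported by `summarize_group()`, so nothing is
  lost if they are read as sd).

## Hemoglobin ligand-form deconvolution

Concentrations (mol/L at 1 cm path, a fixed constant of the model) are
linear in the anchor absorbances $A_{577}, A_{569}, A_{500}$:
$c = \mathbf{C}\,a \cdot 10^{-4}$ with

$$\mathbf{C} = \begin{pmatrix} 1.7 & -1.3 & -0.15\\
                               -1.6 & 2.5 & -0.33\\
                                0.2 & -0.4 & 0.33 \end{pmatrix}
\quad(\text{rows } \mathrm{HbO_2}, \mathrm{Hb}, \mathrm{MtHb}).$$

$\mathbf{C}$ is well conditioned ($\det \mathbf{C} = 0.5565$), and its
scaled inverse $\mathbf{E} = 10^4\,\mathbf{C}^{-1}$ is the model's
*implied* apparent extinction matrix — the provenance of the
coefficients (the underlying millimolar extinction coefficients) is not
documented, so $\mathbf{E}$ should not be confused with a literature
extinction table. The tests verify $\mathbf{E}$ entry-wise against a
hand-written Cramer's-rule inverse and check the forward–inverse round
trip to relative error $<10^{-8}$.

Because $\mathbf{C}$ has negative entries, inconsistent absorbance
triples can produce negative concentrations. These are **flagged and
preserved**; clipping at zero is available but explicit
(`speciate(..., clip = TRUE)`), since silent clipping would hide
miscalibrated inputs. Fractions are reported only when the speciation
is non-negative with positive total.

Full spectra are bridged to the formulas by `anchors_from_spectrum()`
using linear interpolation between bracketing grid points; on the
emulated instrument grid (200–700 nm at 0.1 nm) every anchor is an
exact grid hit, and interpolation error on coarser grids is negligible
relative to photometric noise. A nearest-neighbour mode exists for
exact-grid data.

Other numerical conventions:

* **OD normalization** (`normalize_to_od()`, default target 0.8)
  rescales multiplicatively. The reference wavelength is not part of
  the published convention; the default is the Soret-window maximum
  (380–440 nm) — the most intense heme feature, robust to small peak
  shifts — overridable to any fixed wavelength. The choice is logged
  by the pipeline. The operation is idempotent.
* **Band metrics** (`extract_band_metrics()`) use a plain argmax over
  an optionally boxcar-smoothed trace (default 5 grid points ≈ 0.5 nm);
  derivative-based peak picking was rejected as harder to verify
  against a brute-force oracle. A maximum on a window boundary (flat or
  monotone trace) is reported with a `boundary` flag rather than
  suppressed. Default windows: Soret 380–440, Q-bands 530–552 and
  565–585, aromatic band 270–290 nm.
* **Percent change** follows the "decreased by x%" convention:
  $100\,(A_{control} - A_{treated})/A_{control}$, positive for a
  decrease.

## The synthetic-data generators

The generators define the study conditions the tests exercise; their
defaults are fixed once and not tuned.

**Counts** (`simulate_counts()`): each donor's class counts are
multinomial with `cells_per_donor = 1000` cells (the per-donor counting
depth is not published; 1000 classified cells is a realistic SEM
session) over `n_donors = 30` donors, the published panel size. Class
probabilities default to the reference per-condition percentages
(`reference_probabilities()`; printed columns summing to 99.9–100.1 are
renormalized with a message). Donor heterogeneity is
Dirichlet-multinomial: each donor's probability vector is drawn from a
Dirichlet with concentration 1500, chosen once so that the simulated
between-donor SEM of the discocyte percentage at 30 donors × 1000 cells
is of the order of the published ± values (several tenths of a
percentage point to ~1.5); classes with probability zero stay
structurally absent. `overdispersion = NULL` gives pure multinomial
sampling.

**Spectra** (`simulate_spectrum()`): a noiseless trace is built as
$\sum_s c_s T_s(\lambda)$ from per-species Gaussian band templates
(oxyhemoglobin 415/542/576/280 nm, deoxyhemoglobin 430/555/280 nm,
methemoglobin 406/500/630/280 nm, widths 8–15 nm — literature-standard
positions used purely for realism), then corrected by the unique
quadratic through the three anchor residuals so the noiseless spectrum
evaluated at 577/569/500 nm equals $\mathbf{E}c$ *exactly*. Anchor
consistency therefore never depends on the template shapes. A quadratic
is used because three residuals determine exactly one degree-2
polynomial — deterministic, with no per-species rescaling ambiguity.
Gaussian photometric noise (default sd 0.001 Abs, the emulated
spectrophotometer's photometric repeatability) is added pointwise. With
independent anchor noise the recovered-concentration standard
deviations have the closed form
$\sigma_c = \sigma \cdot 10^{-4}\sqrt{\sum_j C_{sj}^2}$
(`propagated_concentration_sd()`), which the Monte Carlo tests confirm.

What the generators deliberately do **not** emulate: correlated
(wavelength-dependent) instrument noise and baseline drift; scattering
and turbidity of real hemolysates; donor-level correlation between
morphology and hemoglobin state; kinetics of shape transformation or
methemoglobin formation. Passing tests therefore demonstrate
correctness of the computational pipeline under the stated statistical
model, not robustness to every artefact of real recordings. In
particular, published band-intensity decreases for drug-treated
hemoglobin (a few percent at 1 h, ~10% at 24 h) require the original
recorded spectra, which are not publicly deposited; the band-metric and
percent-change operations are validated on constructed spectra instead.

**Chemistry helpers**: `molar_mass()` parses Hill-notation formulas
against embedded IUPAC 2021 conventional atomic weights (the
hydrochloride salt of minocycline, C23H27N3O7·HCl, computes to 493.94
g/mol at 2 decimals). `molarity_from_dose()` is plain
mass/(Mr·volume) arithmetic; the working concentration 8.1×10⁻⁵ mol/L
arises under an *assumed* 200 mg dose distributed in 5 L — an
assumption of this package's documentation, since the published
derivation does not state the dose/volume pair.

## Statistics

`summarize_group()` reports n, mean, sample sd (n−1) and SEM; a single
observation is flagged degenerate with sd 0. `student_t()` is the
classical pooled-variance two-sample test (via `stats::t.test`,
`var.equal = TRUE`), two-sided, with significance declared at
`p ≤ α` (default α = 0.05); Welch and donor-paired variants are
options, pooled and unpaired being the defaults because that matches
the naming and the absence of any pairing statement in the convention
being reproduced. No multiple-testing correction is applied — matching
the reproduced workflow — but the pipeline logs the number of tests
performed. The degenerate case of two equal constant groups returns
t = 0, p = 1. Type-I error calibration is checked by simulation in the
test suite (rejection rate within [0.04, 0.06] of nominal 0.05 under
the null).

## Pipeline and problem sizes

`run_pipeline()` composes the stages deterministically from a validated
YAML/list configuration (unknown keys are rejected; every inferred
convention and defaulted policy is logged to stderr). Reports keep
unrounded values alongside rounded ones, and `write_report()` emits TSV
plus a text block; regeneration from the same config and seed is
bit-identical, with all randomness routed through seeds derived from
the single configured seed and the caller's RNG state left untouched.

Problem sizes used by the test suite — chosen as the smallest sizes at
which the statistical assertions have comfortable margins: parameter
recovery on the full 5001-point grid; noise-propagation Monte Carlo at
400–1000 replicates on a 450–650 nm grid; large-sample multinomial
recovery at 10⁶ cells; type-I calibration at 2×10³–10⁴ null pairs.

## Known limitations

* The deconvolution is exactly the three-anchor linear model; no
  full-spectrum least-squares unmixing, and no extension to other
  hemoglobin species (carboxy-, sulfhemoglobin).
* Indices are undefined for fields with no discocytes; panels where a
  treatment abolishes discocytes entirely need a different summary.
* The taxonomy is flat; no hierarchical or fuzzy class membership, and
  counts must arrive pre-classified (no image analysis).
* The t-test layer assumes approximate normality of per-donor indices;
  no nonparametric fallback or repeated-measures modelling across
  incubation times.
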