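---
title: "Methods: models, parameters and design choices in rumenbatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in rumenbatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumenbatch)
```

## The experimental system

An in vitro rumen batch culture incubates a weighed feed substrate
(default 0.5 g dry matter) with strained rumen fluid (20 mL) and buffer
(40 mL) in sealed bottles at 39 °C. Gas volume is read by syringe at
3, 6, 9, 12, 24, 48 and 72 h; methane fraction of each gas draw is
measured by GC; at 72 h the bottles are opened and pH, VFA, NH₃-N,
microbial protein, residue weight, amino acids, microbial qPCR counts
and 16S community composition are determined. Substrate-free blank
bottles track inoculum-derived gas. The package implements the full
numerical path from these readings to treatment-comparison tables; the
wet-lab steps themselves are out of scope.

## Gas model and blank correction

Net interval gas is gross minus the per-timepoint mean of the blanks;
cumulative gas is the running sum of interval nets, and the 72 h total
divided by substrate mass gives mL/g DM. Two decisions are worth
stating:

* **Negative nets are retained**, not clipped. Clipping would break the
  conservation identity "sum of interval nets = final cumulative value"
  that several tests rely on; a warning counts occurrences instead.
* **Methane interval volume = interval *net* gas × CH₄ fraction** by
  default. Whether the original convention used net or gross gas for
  this product is not recoverable from typical method descriptions, so
  `cumulate_gas(..., ch4_basis = "gross")` offers the alternative.

Replicate screening rejects a bottle when its 72 h cumulative net gas
deviates more than `threshold_pct` (default 10 %) from the group mean.
The reference point — group mean of 72 h cumulative net gas, computed
once before any removal (single pass) — is a package decision; "above
10 % variation" alone does not define a reference statistic. An
infinite threshold disables the filter.

## Hydrogen balance

The Demeyer stoichiometry is linear in the VFA and methane amounts, so
the implementation is a weighted sum and its tests compare against an
independently coded term-by-term accumulation over random profiles.
Decisions:

* **Liquid volume 0.06 L** is the default concentration→amount bridge;
  it reproduces reported "hydrogen produced" values from reported VFA
  concentrations exactly, which fixes the convention.
* **Everything is carried in mmol** (the equations are often written
  in mol; end-point tables report mmol).
* **Methane molar volume is configurable** (22.4 L/mol STP default;
  25.6 L/mol at 39 °C offered). Published "hydrogen utilized" values
  cannot be reproduced from published per-gram CH₄ volumes under either
  convention — the original calculation presumably used unrounded
  per-bottle methane amounts. The package therefore treats methane
  amount as an input and documents the discrepancy rather than tuning
  a conversion to match printed outputs.
* VFA profiles are taken as end-point concentrations; lactate, formate
  and succinate are outside the stoichiometry by construction.

## Fermentation chemistry and amino acids

TVFA is the six-acid sum; the A/P ratio requires propionate > 0; molar
proportions are acid/TVFA. DMD follows the residue formula and flags
(but keeps) negative values. Colorimetric assays are modelled as linear
standard curves only — no reagent-specific math is attempted.

The amino-acid panel groups **histidine with the non-essential block**,
following the reporting convention of the tables this analysis
reproduces rather than the conventional essential assignment. Published
aggregate rows (EAA/NEAA/total) were computed from unrounded inputs, so
column sums of printed values land within about 0.5 % of them; tests
use that relative tolerance for aggregates and exact arithmetic
everywhere else.

## qPCR quantification

Copy numbers use the 660 g/mol/bp double-stranded amplicon constant
(the field's standard, rarely stated explicitly). The dilution chain
from reaction to sample is collapsed into one multiplicative factor
because extraction and elution volumes are assay-specific. Quality
rules — standard-curve R² ≥ 0.999 and efficiency in (0, 1.1] — are
warnings, not hard failures, since they describe achieved assay quality
rather than a validity bound of the arithmetic. Reported units follow
the input labels (log₁₀ copies per mL of sample); no per-gram
conversion is attempted.

## Diversity

Alpha indices follow the Mothur formulations: Shannon −Σp·ln p, Simpson
as the *dominance* form Σnᵢ(nᵢ−1)/(N(N−1)) (so diversity loss raises
the index, matching the ×10⁻² reporting convention), Chao1 with the
classic F₁²/(2F₂) form and the bias-corrected form when F₂ = 0, ACE
with the rare-abundance cutoff fixed at 10 (the Mothur default), and
Good's coverage 1 − F₁/N. ACE is undefined (NA) when every rare taxon
is a singleton. Rarefaction is available (`rarefy_counts()`, seeded)
but indices default to raw counts, since whether rarefaction was
applied upstream is usually unstated.

Bray–Curtis comes from `vegan::vegdist()`. PERMANOVA is implemented
in-package (Anderson's pseudo-F with label permutation and the
(count+1)/(n+1) p-value convention) so that the permutation stream is
seed-controlled and cheap enough for null-calibration tests; tests
cross-check the observed pseudo-F and R² against `vegan::adonis2()`.
The permutation count defaults to 999 and is a parameter, since both
999 and 9999 are common.

## Group statistics

The experimental unit is the run-level mean of the retained bottles of
one treatment (n = 2 runs per treatment in the default design). ANOVA
is one-way; pooled SEM is √(MSE/n). Compact letters are driven by
**Tukey HSD** (the post-hoc procedure is an explicit choice; the
original analysis names only a general linear model) through an
insertion–absorption algorithm on the pairwise significance matrix,
with letters assigned in descending-mean order starting at "a". At
n = 2 units per group, letter recovery is power-limited; the letter
pattern of a strongly separated contrast such as A/P
(1.79/2.20/1.86/2.31, SEM 0.01) is recovered in >90 % of simulated
experiments, but subtler contrasts need bottle-level analysis, which
the functions support by simply passing bottle-level data. When
within-group variance is numerically zero the Tukey machinery is
bypassed: groups differ iff their means differ.

Spearman correlations use average ranks on ties, stars follow the
`*`/`**`/`***` p-bands gated on |ρ| > 0.1, and **no multiple-testing
correction** is applied — matching the stated star rules of the
heatmaps this reproduces.

## The synthetic-data generator

The generator defines the study conditions: 4 treatments × 5 bottles ×
2 runs, 3 blanks per run, readings at {3, 6, 9, 12, 24, 48, 72} h,
0.5 g substrate, 60 mL liquid. Design choices:

* **Gas curves** follow the single-pool saturating form
  V(t) = A(1 − e^(−kt)) — the simplest monotone family consistent with
  the described steady-then-plateauing cumulation. Preset asymptotes
  are the reported 72 h mL/g totals × 0.5 g; the rate constant 0.08/h
  puts ~62 % of gas before 12 h and ~98 % before 48 h, matching the
  described time course. No kinetic fitting is performed on the
  analysis side.
* **Noise models**: multiplicative lognormal (unit mean) on gas
  intervals, additive Normal truncated at 0 on end-point chemistry,
  additive Normal on Ct. Positivity plus simplicity.
* **Per-bottle sds** are back-derived from published pooled SEMs as
  SEM·√2, treating the 2 run-averages as the units behind the SEM. This
  is a reconstruction — within-bottle error magnitudes are not
  published — and is flagged as such.
* **CH₄ fractions** are constant across intervals at the treatment's
  CH₄:gas volume ratio (0.122/0.087/0.115/0.082). Real nitrate
  treatments suppress early methane disproportionately; the constant
  fraction reproduces totals, not curve shapes.
* **OTU tables** are Dirichlet-multinomial around 16-taxon genus-level
  composition presets (15 reported major genera + "other");
  concentration 200 gives realistic within-group compositional spread.
  Row sums equal the configured depth exactly.
* **Seeding**: one global seed feeds an independent substream per table
  (derived deterministically from seed and table name), so generating
  an additional table never perturbs earlier draws, and identical seeds
  give byte-identical datasets.

What passing tests on these data do **not** show: behaviour under real
16S read noise (chimeras, sequencing error, compositional artefacts of
clustering), mechanistic nitrate reduction kinetics, correlated error
across assays from shared inoculum, or non-Normal heavy-tailed assay
error. The generator emulates the statistical shape of the experiment,
not its chemistry.

## Numerical choices and degenerate inputs

* Zero-variance ANOVA inputs bypass Tukey (see above); MSE below
  1e-10 × total variance counts as zero.
* All-identical samples give PERMANOVA pseudo-F = 0, p = 1 rather than
  0/0.
* Truncated-Normal draws use rejection sampling, so a zero-mean
  quantity yields strictly non-negative values without a point mass
  from clipping.
* Perfect linear fits report R² = 1 without relying on `summary.lm`
  warnings.
* Rounding happens only at presentation; all pipeline arithmetic is
  double precision.

## Problem sizes used by the test suite

Stochastic suites run at sizes chosen to make their expected error
bands meaningful: hydrogen-balance oracle equivalence over 1000 random
profiles; richness-estimator dominance over 1000 random samples;
PERMANOVA type-I calibration over 1000 null datasets (12 samples, 99
permutations each); Spearman star-band null rate over 2000 simulations
at n = 8 (exact enumeration of the 8! rank permutations gives a band
probability of 0.0386, so the observed rate is checked against
0.04 ± 0.02); and mean-recovery over 50 simulated noisy experiments.

## Known limitations

* Published "hydrogen utilized" cannot be regenerated from published
  per-gram methane volumes (see above); the package computes it from
  the methane amount it is given.
* Letter patterns of the original tables cannot be regenerated exactly
  without the raw data; letter logic is validated on synthetic data
  against its defining invariants instead.
* The deposited sequencing reads (and therefore observed OTU richness,
  Table-scale diversity values and relative abundances) are outside
  desk scale; the diversity code is validated by construction and
  property, not by re-analysis of the deposit.
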