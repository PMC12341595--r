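---
title: "From plate fluorescence to ACMG/AMP classes: methods behind abca1fc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From plate fluorescence to ACMG/AMP classes: methods behind abca1fc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abca1fc)
```

## The problem

ABCA1 exports cellular cholesterol and phospholipids to apolipoprotein A1,
the first step of reverse cholesterol transport. Loss-of-function missense
variants reduce plasma HDL cholesterol (familial HDL deficiency; biallelic
loss causes Tangier disease), but most reported variants have never been
functionally characterized, leaving them as class 3 (uncertain significance)
in clinical ACMG/AMP assessment. `abca1fc` implements the full analysis
chain that turns a fluorescence-based cholesterol efflux assay into
gene-calibrated classification evidence: plate statistics, functional
categories, cell-surface mechanism calls, chaperone-rescue flags, domain and
motif annotation, NBD1/NBD2 equivalence mapping, and a five-tier ACMG/AMP
evidence combiner.

## The efflux statistic

For a well-set measured in triplicate, the efflux fraction is

$$ \mathrm{efflux} = \frac{\overline{\text{medium}}}
   {\overline{\text{medium}} + \overline{\text{lysate}}} $$

Two background corrections follow, in order: the no-acceptor efflux of the
same construct and experiment is subtracted (HDL-nonspecific leakage), then
the leakage-corrected efflux of mock-transfected cells in the same
experiment (ABCA1-nonspecific efflux). The resulting *specific efflux* is
expressed per experiment as a percentage of the same experiment's WT
specific efflux, and the per-experiment percentages are summarized as mean
and SD across (typically four) independent experiments.

Aggregation order is a genuine design choice: the source data could also be
normalized on pooled means. We fix within-experiment normalization because
the statistic is a ratio — it cancels plate-to-plate scale (exposure,
loading, transfection batch) exactly, which the test suite verifies as an
invariance of the pipeline to arbitrary per-experiment rescaling of all
signals. Negative corrected efflux is retained (not clamped) so that
mock-level constructs scatter symmetrically around zero.

Significance against WT uses a two-sample t-test gated by an F-test for
equal variances at level 0.05 (pooled variance when the F-test does not
reject, Welch otherwise; two-tailed unless stated). Because the normalized
WT is exactly 100 in every experiment, the test is computed on the
*pre-normalization* specific efflux values of variant vs WT — the only
scale on which a two-sample comparison is well defined. No multiple-testing
correction is applied; p-values are reported as-is.

### Functional categories

Mean relative efflux below **41%** of WT is loss-of-function (the efflux of
the well-documented pathogenic control p.W590S), above **80%** functionally
normal (anchored by p.I883M at 84% and p.V2244I at 75%), and anything in
between uncertain. Both outer thresholds are exclusive, so a mean of exactly
41 or 80 stays uncertain. An optional, clinically anchored alternative
loss-of-function cutoff of **58%** (the highest efflux among uncertain
variants found in Tangier patients, p.R2080Q) can replace the 41% cutoff;
with the same exclusive boundary, a variant at exactly 58% remains
uncertain. All cutoffs live in `calibration_config()`, never in logic.

## Cell-surface quantification and mechanism

Raw surface level is the biotinylated-surface band over the beta-actin
loading band, relative to WT's same ratio in the same experiment. Corrected
surface level divides by the total-ABCA1 band instead — total ABCA1 is its
own denominator, so the loading control cancels and is not reapplied. A
construct whose *corrected* level is significantly below WT (one-sided
F-gated t-test at 0.05) is called transport-deficient; one whose raw level
is reduced while the corrected level is not is degradation-prone. The
published 50% figure is kept as a *severity flag* on the relevant
percentage, not as the significance rule: the source describes "reduced"
without stating a test, so operationalizing it as a one-sided test is this
package's documented choice.

## 4-PBA rescue and suspected ATPase deficiency

Rescue is a one-tailed (increase) F-gated t-test of relative efflux under
10 mM 4-PBA vs vehicle, each normalized to the mock-treated WT of the same
experiment (dose and duration are metadata, not model inputs). A variant is
flagged as suspected ATPase-deficient when three conditions hold: it is
*not* rescued, its cell-surface level *does* increase significantly
(one-tailed, 0.05) under 4-PBA, and it lies in a Walker A, Walker B or
signature motif. The flag deliberately encodes no "extreme reduction"
cutoff (descriptions like "10% or less" are left descriptive); rescued
variants are never flagged, which the tests assert as a logical exclusion.

## Domain map

The shipped map (`abca1_domain_map()`) encodes only ranges with published
residue bounds: NBD1 903–1147 and NBD2 1907–2143 with their Walker A
(926–942 / 1939–1955), Walker B (1056–1065 / 2068–2077) and signature
(1033–1040 / 2045–2052) motifs, R domains 1182–1251 and 2155–2220, and
coupling helices IH1 3–20, IH2 667–673, IH3 1327–1344, IH4 1684–1690.
Positions outside these ranges map to `"linker/other"`; ECD/TMD ranges are
intentionally not invented. Ranges are inclusive and 1-based on the
NM_005502.4 product. Region assignment is a partition (validated:
non-overlapping ranges), and motif ranges are validated to sit inside their
parent NBD.

## ACMG/AMP evidence combination

Criterion tokens (`PM2`, `PP4_strong`, `PM1_supporting`, ...) carry their
code's native strength unless suffixed. Three criteria are derived by rule
rather than asserted:

* frequency — filtering allele frequency ≥ 0.005 gives BA1, ≥ 0.002 BS1,
  ≤ 0.0002 PM2 (gene-specific calibration; boundaries inclusive);
* phenotype — PP4 supporting below HDL-C 0.5 mmol/l, moderate below 0.3,
  strong below 0.1 or with Tangier disease, strictest tier winning;
* function — the efflux category maps to PS3 (loss-of-function) or BS3
  (normal) at the strength the assay qualifies for: moderate when it has
  normal and null controls, replicates, and at least 11 class-1/2/4/5
  variant controls (`validate_assay()`), supporting otherwise.

When a derived criterion collides with an asserted one on the same code,
the asserted token wins — explicit curation outranks the rule.

Combining follows the standard ACMG/AMP tables, frozen as code and pinned
by a golden test over the twelve published reclassification rows and by an
exhaustive comparison against an independent, data-driven brute-force rule
evaluator over every evidence multiset of size ≤ 4. Two deliberate
generalizations: any benign criterion applied at moderate strength counts
as two supporting benign criteria (the ClinGen equivalence stated for
BS3_moderate), and any situation where both a pathogenic and a benign rule
fire resolves to class 3. PVS1/PS1-style criteria are accepted as asserted
tokens but never derived here (no transcript-level analysis in scope).

Worked examples: `{PM2, PM3, PP3, PP4_strong}` is likely pathogenic
(class 4); adding PS3_moderate makes 1 strong + 3 moderate — pathogenic
(class 5). `{BS1}` alone is class 3; adding BS3_moderate (= two supporting
benign) meets the likely-benign rule (class 2).

## NBD1/NBD2 equivalence mapping

The two NBDs are aligned over the windows 923–1121 and 1936–2134 by
deterministic global pairwise alignment (Needleman–Wunsch as implemented in
`Biostrings::pairwiseAlignment`) with BLOSUM62, gap open 10 and gap extend
0.5. Every matched column becomes a position pair in full-protein
coordinates; a pair is *conserved* when the residues are identical, and a
variant is mirrored into the opposite domain only at conserved pairs
(`equivalent_variant()`). Identity is the fraction of identical pairs over
all alignment columns; *similarity* is the fraction of pairs with a
positive BLOSUM62 score, gaps counted in the denominator — the source does
not define its similarity measure, so this one is fixed explicitly and the
published 39% figure is treated as a regression anchor rather than an exact
target. One published pair (p.G948R/p.G1916R) crosses the other pairs and
falls outside the NBD2 window, so no monotone alignment can produce it; it
is flagged `alignment_consistent = FALSE` in `abca1_equivalent_pairs()` and
excluded from recovery tests. The reference ABCA1 protein sequence is not
bundled; `align_nbds()` takes any user-supplied sequence, and the alignment
properties are exercised on synthetic duplicated-domain sequences with
planted ground truth.

## Synthetic data

The generator emulates the assay design: per construct × experiment ×
condition a well-set total signal $T \sim \mathrm{LogNormal}(\log s,
\sigma_\text{jitter})$ is split into medium $= T f \varepsilon$ and lysate
$= T(1-f)\varepsilon'$, with independent per-well noise $\varepsilon \sim
\mathrm{LogNormal}(0, \sigma)$ on each triplicate value. The acceptor-well
fraction is

$$ f = \ell + \nu + \frac{a}{100}\,(f_{\mathrm{WT}} - \ell - \nu), $$

where $\ell$ is the no-acceptor leakage fraction (default 0.05), $\nu$ the
mock (ABCA1-nonspecific) efflux above leakage (0.02), $f_{\mathrm{WT}}$ the
WT acceptor fraction (0.30) and $a$ the construct's true activity in
percent of WT; no-acceptor wells use $f=\ell$ and mock acceptor wells
$f=\ell+\nu$. This parameterization makes the pipeline's
$(\text{construct}-\text{mock})/(\text{WT}-\text{mock})$ estimator invert
the truth *exactly* at zero noise, which the tests assert. The raw
fractions $f_{\mathrm{WT}}$, $\ell$ and $\nu$ are fixtures — no published
values exist for raw fractions, only for WT-relative activity — and truth
fractions are clipped to $[0,1]$. Multiplicative log-normal noise is the
natural choice for fluorescence analyzed as ratios, and the per-experiment
scale jitter is harmless by construction (the statistic is
scale-invariant), which is itself a tested property. Defaults follow the
emulated design: four independent experiments (five for rescue), triplicate
wells, per-well $\sigma = 0.10$.

Surface truth is specified per variant as (raw %, corrected %) of WT and
inverted through band intensities; rescue profiles (`rescuable`,
`atpase_deficient`, `unaffected`) raise efflux by a fixed gain under 4-PBA
for rescuable variants only, while surface bands respond for all but
`unaffected` profiles. All generators are bit-identical under a fixed seed.

What the generator does *not* emulate: plate spatial or edge effects,
instrument drift, kinetic time-courses, or correlated well noise. Passing
the recovery tests therefore shows the estimator chain is correct under the
stated noise model, not that the wet-lab assay itself is unbiased.

### Study-scale fixtures

The shipped 74-variant study table (`abca1_synthetic_study()`) is a clearly
labelled synthetic reconstruction: means, SDs and criteria printed for
individual variants are used verbatim, and the remaining rows are invented
under the reported aggregate constraints (15 loss-of-function, 35 normal,
24 uncertain; 58 of 74 at class 3 before functional evidence; three
uncertain variants placed at exactly 58% so that exactly the three variants
printed below 58% move under the alternative cutoff with its exclusive
boundary). Four replicate values per variant are derived deterministically
from fixed z-scores so that their mean and sample SD reproduce the
tabulated values exactly. Conclusions about individual synthetic rows are
meaningless; only the aggregate structure is informative.

## Numerical choices and problem sizes

* Thresholds are compared with strict inequalities for the outer categories;
  ties therefore fall to `uncertain`.
* Zero-variance groups in the t-test machinery (possible only with
  noise-free synthetic data) short-circuit to p = 1 for equal means and 0
  otherwise, reported as `"degenerate"`.
* Duplicate criterion codes are rejected rather than deduplicated, making
  `combine_criteria()` idempotent on code sets by construction.
* The category-recovery property runs 200 seeded replications of a
  six-variant, four-experiment plate at per-well noise 0.05, with true
  activities at least five percentage points from both cutoffs — the design
  margin at which the estimator's across-experiment SE (about 2–3 points)
  makes misclassification vanishingly rare. Alignment properties use
  domains of length 50–100 at divergences up to 0.4.

## Limitations

* Only the missense HGVS-p subset used in this assay is parsed; no
  genome-coordinate or transcript mapping.
* PM3 phasing, in-silico predictors (PP3/BP4) and population frequency
  computation are upstream inputs, never derived.
* The 58%-cutoff and mechanism-call operationalizations are this package's
  documented choices where the source assay left them informal.
* With the exclusive-boundary rule, a variant at exactly the alternative
  cutoff does not move categories; users who want the inclusive reading can
  set `alternative_lof_threshold` marginally above 58.
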