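---
title: "Comparing GC-MS body-odor sampling methods with vocompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing GC-MS body-odor sampling methods with vocompare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocompare)
```

## The problem

Untargeted GC-MS profiling of mammalian body odor faces a method-selection
problem: cotton swabs, adsorbent thermal-desorption (TD) tubes and mobile
GC-MS devices each capture a different, partially overlapping slice of the
volatilome, with method-specific sensitivity, boiling-point coverage and
contamination background. Because raw chromatograms from different
instruments are not directly comparable (different columns, temperature
programs, detectors), the comparison has to happen at the level of
*consensus compounds* per method, aligned across instruments by robust
invariants — elution order and diagnostic fragment ions — rather than by
absolute retention times.

`vocompare` implements that workflow end to end and pairs it with a
synthetic-data generator that emulates the study design the analysis
assumes, so every stage can be validated against known ground truth.

## Consensus compounds ("RT ranges")

Peaks of one method that recur within a narrow retention-time span across
samples are treated as one compound. We operationalize "narrow span" as
**gap-based single linkage**: peaks sorted by RT are split wherever the
gap between consecutive peaks exceeds `rt_tol`. This is exactly the
transitive closure of the relation |RT_i − RT_j| ≤ `rt_tol` — the simplest
deterministic rule consistent with the definition, and the one our tests
verify against a brute-force connected-components oracle.

Two further rules complete the stage:

* **One peak per sample per cluster.** One compound produces one peak per
  chromatogram, so if a sample contributes several peaks to a cluster, the
  peak nearest the cluster median stays (ties toward earlier RT) and the
  surplus is reassigned to the nearest cluster not already containing that
  sample, falling back to a new singleton. Each reassignment strictly
  reduces the number of violations, so the procedure terminates.
* **Occurrence filter.** A cluster is kept only if present in at least
  `min_frac` (default 0.5) of the method's samples, with a ceiling rule on
  odd totals (5 of 9 passes, 4 of 9 does not).

**Blank correction.** Animal-sample clusters are compared with
blank-sample clusters of the same method within `rt_tol`; a cluster
survives if its mean area exceeds that of the nearest matched blank
cluster, or if no blank counterpart exists (absence from blanks being the
strongest evidence of animal origin). The comparison statistic is the
cluster *mean* area; the median or maximum would be defensible too, and
the choice matters only for heavy-tailed area distributions — mean was
chosen to be consistent with the mean-area reporting used elsewhere in the
workflow.

`rt_tol` defaults to 0.05 min. Laboratory GC peak widths are a few
seconds; replicate RT drift on one instrument is of the same order, so
0.05 min separates compounds a unit-resolution method can resolve while
absorbing replicate jitter. It is configurable throughout.

## Annotation

Spectral similarity uses the familiar 0–999 library-search match factor:
sticks are weighted `intensity^0.5 · mz^1` (the classic weighting that
up-weights the more diagnostic high-m/z fragments of EI spectra), paired
greedily by nearest m/z within `mz_tol` (default 0.3 u, appropriate for
unit-resolution quadrupole data), and scored as 999 × weighted cosine;
unpaired sticks contribute zero overlap but count in the norms, so
self-match is exactly 999 and disjoint spectra score 0. The exponents are
configurable; the defaults are a design choice, since the commercial
match factor has no single published formula.

A cluster is **named** when one library entry is the top hit with score
above `min_score` (default 700) in *more than* `majority_frac` (default
0.5) of the cluster's member samples. The majority is counted over the
cluster's member samples, not over all samples of the dataset — the
per-RT-range reading of "the majority of all samples"; ties on the vote
count break toward the higher mean winning score. Only the top hit is
considered a vote; counting any above-threshold hit in the candidate list
is a plausible alternative the interface could accommodate, but the top
hit is the stricter and simpler rule.

**Volatility** splits at a boiling point of 250 °C at 760 mmHg, with the
boundary value assigned to the semi/non-volatile class because volatility
is defined by the strict inequality bp < 250 °C. Boiling points quoted
with a ± uncertainty classify on the central value. **Origin** (exogenous,
potentially endogenous, potentially metabolized, unclassified) is a
case-insensitive lookup in a curated metadata table; unknown names and
unrecognized labels map to unclassified.

## Cross-instrument overlap

Absolute RTs are incomparable across instruments, but elution order on
similar stationary phases is conserved up to local inversions, and EI
fragment ions are instrument-independent. Candidate pairs are clusters
sharing at least `n_diagnostic` (default 2) of their `k` (default 8) most
intense consensus-spectrum ions within `mz_tol`; among candidates, the
final pairing is the maximum-cardinality matching whose pairs are
strictly increasing in both RT sequences, computed by
longest-increasing-chain dynamic programming (O(m²), deterministic; ties
on chain length break toward higher summed shared-ion intensity
agreement). Tests verify the DP against exhaustive enumeration on small
instances.

Matches are validated with **Spearman rank correlations**: of the two RT
sequences (a correct assignment gives rho near 1) and of the relative
mean areas (which quantifies whether the two methods share a response
pattern). Rho uses average ranks for ties. For n ≤ 9 the p-value is exact,
from the full n! permutation distribution; above that, the t
approximation on n − 2 df is used, with |rho| = 1 reported as p = 0. A
side with zero rank variance yields a degenerate result (rho = NA with an
explanatory status) rather than a number.

For tables of paired RTs that contain order-discordant compounds,
`concordant_chain()` drops the minimum number of pairs needed to restore
a common elution order (a longest order-concordant chain). On the shipped
18-compound mobile-vs-TD table exactly one compound is discordant —
2-methylheptane and toluene swap order between the instruments, and
either removal restores monotonicity; the chain tie-break keeps the
earlier-eluting candidate, dropping 2-methylheptane — leaving 17 pairs
with rho = 1.

## The abundance model

Whether the compounds shared by two methods are simply the abundant ones
is tested on **relative areas** — each peak's area divided by the sum of
all peak areas in its chromatogram ("peak sum") — natural-log transformed.
The model, fitted by maximum likelihood with `lme4::lmer`, is

    log(relative_area) ~ set + (1 | sample) + (0 + set | sample)
                             + (1 | animal) + (0 + set | animal)

with `set` ∈ {common, unique}: a fixed set effect plus uncorrelated
random intercepts and set slopes for sample and for animal (the
uncorrelated parameterization is the standard convergence-friendly
choice at small group counts). The set effect is tested by a
likelihood-ratio test against the null that drops the *fixed* effect and
keeps the full random structure — χ² = 2·ΔlogLik on 1 df. (Descriptions
of this design sometimes call the dropped term a "random effect sample
set"; sample set is the fixed predictor, and the LRT on it requires ML,
not REML, fits.) Non-convergence is reported as a flag on the result,
never silently replaced by a simpler model; an exactly constant response
short-circuits to the exact answer χ² = 0.

### Calibration

`simulate_area_records()` generates records from the model's own
data-generating process for calibration and power studies. Two defaults
deserve comment:

* `sd_compound = 0`: the model — like the standard field analysis —
  carries no compound-level random effect, so compound-to-compound
  abundance heterogeneity in the null generator would not test the
  implementation but the model's robustness to misspecification (it
  inflates the type-I error through pseudo-replication across compounds).
  The knob is exposed precisely so users can study that effect.
* `sd_slope = 0.05`: with only 6 animals and 12 samples, large true
  random-slope variance makes the χ²(1) reference for the fixed-effect
  LRT anticonservative — a known small-sample property of mixed-model
  LRTs, not an implementation issue. The default keeps slope
  heterogeneity small enough that the reference distribution holds; at
  `sd_slope = 0.2` the empirical type-I error roughly triples, which is
  reproducible with the same function.

At these defaults the test suite verifies a 500-simulation empirical
type-I error within [0.02, 0.09] at α = 0.05, and recovery of an injected
+2 log-unit shift within ±0.3 with p < 0.01 in ≥ 90% of 20 seeds.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` draws a latent panel (default 60 compounds, boiling
points uniform on 80–400 °C to span both sides of the volatility
threshold; log-normal abundances; 6–25-stick EI spectra) and observes it
through each method:

* **Design**: 6 animals × 2 replicates = 12 samples per method (10 for
  the XAD-4-style method), 3 blanks per method — the per-method blank
  count is a free choice, as typical studies run a handful.
* **Detection**: logistic in mean log abundance with intercept
  `qlogis(sensitivity)`, so a panel-average compound is caught with
  probability = sensitivity, detection probability rises with abundance
  (the mechanism by which a less sensitive instrument sees only the
  abundant compounds), and sensitivity 1 means certain detection — which
  is what makes the exact recovery scaffold (cluster count = detectable
  set size) well-defined.
* **Coverage**: a compound appears in a method's samples only if its
  boiling point lies in the method's volatility window.
* **RT**: strictly increasing affine-plus-curvature maps per instrument
  with Gaussian jitter (default 0.01 min), so zero-jitter elution order
  is exactly preserved across methods.
* **Contamination**: exogenous compounds are exactly the ones emitted
  into blanks, at twice the sample-level mean area, plus
  Poisson-distributed spurious noise peaks — giving the blank filter both
  true positives and true negatives.
* **Panel spacing**: consecutive elution coordinates keep a minimum gap
  (0.12 units), reflecting finite chromatographic peak capacity; truly
  co-eluting compounds are not separable by any peak-table method, so
  they are not part of the recovery benchmark.

Reproducibility is strict: all randomness derives from one master seed
via a counter-based per-method/per-stage split, and identical seed +
configuration gives byte-identical outputs.

The generator does **not** emulate: profile-mode raw signal (peak
picking is upstream of the package boundary), retention-index
calibration, co-elution and deconvolution artifacts, bacterial
metabolization dynamics, or instrument drift within a batch. Passing
tests on synthetic data therefore demonstrate the correctness of the
pipeline's logic under its stated assumptions, not the field performance
of any sampling method on real chromatograms.

## Problem sizes used by the test suite

The shipped suites run at the study's own scale: oracle equivalence on
100 random clustering instances up to 200 peaks and exhaustive matching
checks up to 12 candidate pairs; exact consensus recovery over 3 seeds
and jittered recovery over 20 seeds × 5 methods; mixed-model calibration
over 500 null simulations and 20 effect-recovery seeds at 6 animals × 12
samples × 24 compounds (~290 records per fit).

## Known limitations

* The blank filter compares mean areas without a variance model; a
  compound genuinely present in animals but heavily contaminating the
  materials can be removed.
* Annotation trusts the library: a compound absent from the library can
  only be "unknown", and decoy entries with near-identical spectra can
  steal votes below the match threshold.
* The overlap matcher assumes global elution-order preservation; columns
  of very different polarity, which reorder analyte classes wholesale,
  would need retention-index anchoring instead.
* The LRT p-value relies on the χ²(1) asymptotics discussed above; for
  very small designs a parametric bootstrap would be preferable.
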