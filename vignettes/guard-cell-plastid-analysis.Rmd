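---
title: "Guard-cell plastid morphometry and the random-pairing null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guard-cell plastid morphometry and the random-pairing null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gcplastid` quantifies plastid populations in stomatal guard cells (GCs) of
*Arabidopsis* chloroplast-division mutants and asks whether the two GCs of
a stoma — sisters from one symmetric guard-mother-cell (GMC) division —
share their plastid phenotype more often than chance. This vignette is the
package's account of the models and the choices behind them.

```{r setup}
library(gcplastid)
```

## The classification layer

Three deterministic rules, applied per plastid or per GC:

* **Size classes.** Chloroplast body length partitions into
  mini (< 2 µm), normal (2–6 µm) and giant (> 6 µm). The boundary
  convention is half-open: exactly 2 µm and exactly 6 µm are *normal*, so
  the giant class is strictly above 6 µm. Lengths must be finite and
  positive; anything else is a validation error, not a silent `NA`.
* **GC types.** A GC is type 1 if it contains at least one chlorophyllous
  giant plastid, else type 2 if it contains a chlorophyllous normal-sized
  plastid, else type 3 if it contains no chloroplast at all. The taxonomy
  has no slot for a GC whose only chloroplasts are mini-class — such cells
  have not been observed in leaf stomata — so they receive an explicit
  `mini_only` label plus a warning rather than being coerced into a type.
  Treating the gap as a data-quality signal keeps an empirical regularity
  checkable instead of baking it in.
* **Morphology classes.** Class IV if any plastid is annotated reticulate
  (part of a web-like, entirely tubulated chlorophyll-less structure);
  else III if every plastid is mini and chlorophyll-less; else I if every
  plastid is a normal-sized chloroplast; else the residual class II.
  "Numerous" mini-plastids in class III is deliberately not turned into a
  count threshold — the class is compositional, and the plastid count is
  reported separately. Class II is the residual because its published
  description ("often" giant or minute plastids) does not pin down a
  predicate. Chlorophyll status and the reticulate flag are *inputs*
  (from autofluorescence imaging and visual annotation); the package never
  infers either from length.

Two invariants tie the layers together and are enforced in tests: a class
III or IV GC is always type 3 (those plastids are chlorophyll-less), and
every type-1 GC contains a giant chloroplast.

## The random-pairing null

The pair-level question is whether like-typed GCs co-occur within stomata.
The null keeps each genotype's single-GC type counts `n_t` fixed
(`N = n_1 + n_2 + n_3 = 2P` cells) and pairs the cells by a uniform random
perfect matching: shuffle the `N` labelled cells, pair consecutive
elements. Equivalently, every one of the `(N−1)!!` matchings is
equally likely. Under this null the expected pair-type counts are

$$E[t/t] = \frac{n_t (n_t - 1)}{2(N-1)}, \qquad
  E[s/t] = \frac{n_s n_t}{N-1} \ (s \neq t),$$

which sum to `P`. `expected_pair_counts()` implements the closed form;
`simulate_random_pairing()` implements the Monte-Carlo version (default
1,000 trials over 100 pairs, the scale of the original resampling
analysis) and the two act as mutual oracles — the test suite also checks
both against exhaustive enumeration of all matchings for `N ≤ 8`.

`pairing_preference_test()` reports, per pair type, the z-score against
the simulated mean and SD (flagged undefined when the null SD is zero,
e.g. a single-type population) and one-sided empirical p-values with the
add-one convention, `p_enrich = (\#\{trials \ge observed\} + 1)/(T + 1)`,
so no p-value is ever exactly zero and the smallest resolvable value at
`T` trials is `1/(T+1)`. The six pair types are reported raw, without
multiple-testing correction: the analysis is descriptive of one
pre-specified contrast (type3/type3 enrichment, hybrid avoidance), and
consumers can correct downstream if they test many genotypes.

Every simulation takes an explicit integer seed, records it in its result
and in the JSON sidecar of any file written, and restores the caller's RNG
state, so identical inputs and seed give bit-identical output.

## The synthetic generator

No raw measurement tables were deposited with the original study, so the
package ships a generator whose presets are *calibrated to the published
summary statistics* of each genotype — type frequencies, chloroplasts per
GC (WT 5 ± 1, clamp [3, 7]; *arc5* 4 ± 1; *arc6* 2 ± 2; *atminE1* 3 ± 1),
pooled size-class fractions, and pooled length moments (e.g. WT
4.3 ± 0.8 µm, *arc6* 5.2 ± 3.1 µm). Printed type-percentage vectors that
sum to 101% (both *arc6* 43/36/22 and *atminE1* 71/21/9) are normalised.

Per stoma: with probability κ one GC type is drawn from the line's type
probabilities and assigned to both cells, otherwise each cell draws
independently — the simplest mechanism that produces positive pair
concordance (the GMC hypothesis: some mother cells carry only
chlorophyll-less plastids) while leaving the single-GC marginal exactly
equal to the type probabilities for any κ. κ has no measured value; the
mutant presets default to 0.5 and WT to 0, and the parameter is exposed
for sensitivity analyses rather than asserted as an estimate.

Per GC, given its type:

* chloroplast counts are rounded, clamped normals. The location is solved
  (root finding on the exact clamped-count mean) so that the mean over
  *all* GCs — type-3 cells contribute zero — equals the printed per-GC
  mean. Clamp ranges besides WT's printed [3, 7] are generator choices
  (*arc5* [1, 8], *arc6* [1, 9], *atminE1* [1, 8]).
* lengths are truncated normals per size class, again solved so the
  *post-truncation* means hit their targets; naive truncation of a
  N(4.3, 0.8) to [2, 6] would bias the WT mean by ≈ 0.03 µm, which is
  material at the n of a calibration test. The normal-class mean is the
  free parameter solved from the pooled length-mean constraint given the
  structural class mix; giant and mini component means and SDs are fixed
  per line at plausible mid-range values. Component bounds stay 0.05 µm
  clear of the 2 µm and 6 µm class boundaries so that rounding lengths to
  the reported 0.01 µm precision can never flip a size class.
* type-1 GCs carry `1 + Binomial(n − 1, p_g)` giants, with `p_g` solved so
  the pooled giant fraction matches the published size-class table. This
  reconciles an inconsistency in the published numbers: under proportional
  sampling of chloroplasts, a line's giant-chloroplast fraction implies
  more than one giant per type-1 GC in the mutants (e.g. ≈ 1.5 in *arc6*,
  ≈ 2.8 in *arc5*). For WT the two printed numbers cannot be reconciled at
  all (they would require every chloroplast of a type-1 GC to be giant),
  so `p_g` is capped at 0.6 and the WT pooled giant fraction settles at
  ≈ 0.34% rather than the printed 0.5% — the only calibration target the
  generator knowingly misses.
* type-2 GCs force their first chloroplast to be normal-sized (the type
  must be realisable); the per-chloroplast mini probability is solved over
  the *eligible* slots so the forced draw does not bias the pooled mini
  fraction.
* type-3 GCs hold `5 + Poisson(10)` chlorophyll-less mini-plastids
  ("numerous", but no count was published), reticulate as a whole-cell
  Bernoulli event (0.3 in *arc6*/*atminE1*, where class IV was observed;
  0 in *arc5* and WT). Mutant type-1/2 GCs also carry
  `Poisson(0.3–0.8)` chlorophyll-less plastids, reflecting the mixed
  populations of class II cells.

What the generator does *not* emulate: measurement error and detection
limits near the microscope's resolution, within-leaf spatial structure,
correlations between sister GCs beyond the shared type draw, and any
mechanistic model of plastid division or bulging. Tests passing on
synthetic data therefore validate the pipeline's arithmetic and the
statistical calibration of the null — not biological claims about real
populations.

## Problem sizes and tolerances

Calibration tests generate 1,000 stomata per line (≈ 2,000 GCs, ≈ 4,000 –
10,000 chloroplasts) and require each recovered statistic to sit within 3
standard errors of its target; Monte-Carlo/closed-form agreement is
checked at 10,000 trials within 3 Monte-Carlo SEs; the type-I error of the
enrichment p-value is estimated from 200 replicate κ = 0 experiments of
100 pairs at 999 trials each, and is required to lie in [0.02, 0.09]
around the nominal 5%. The enumeration oracle is used up to `N = 8`
(105 matchings). These sizes keep the full suite under a minute while
leaving the 3-SE bands narrow enough to catch the biases the calibration
machinery exists to remove.

## Known limitations

* The generator's per-type count distribution is shared between types 1
  and 2 within a line; the published per-type count breakdown (not
  printed) may differ.
* Integer type counts for the *arc6* and *atminE1* null analyses at
  `N = 200` are reconstructed from rounded percentages (adjusted on the
  residual type-2 slot to total 200); the *arc5* counts are printed
  exactly.
* The published pair-level observed counts (bar heights) are not available
  as numbers, so observed-vs-null comparisons on real data cannot be
  reproduced; the workflow demonstrates them on concordant synthetic
  populations instead.
* One published frequency-table column (*arc6*) is internally inconsistent
  (counts 64 + 102 + 35 = 201 against a printed total of 200, and
  35/200 ≠ the printed 17.0%); the package computes exact percentages and
  uses the 34-mini reading where a consistent column is needed.
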