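# gcplastid

Quantitative analysis of plastid populations in stomatal guard cells (GCs)
of *Arabidopsis thaliana* plastid-division mutants (*arc5*, *arc6*,
*atminE1*).

In these mutants, chloroplast division is impaired and leaf guard cells
carry anything from a single giant chloroplast to swarms of
chlorophyll-less mini-plastids. Because the two GCs of a stoma arise from
one symmetric division of a guard mother cell, the way plastids are
partitioned between the two sister cells is informative about when and
where plastid differentiation goes wrong. `gcplastid` provides the full
quantification pipeline for this question, for anyone working from
per-plastid measurement tables (genotype, stoma, guard cell, plastid
length, chlorophyll autofluorescence status):

* **Classification** — chloroplast size classes (mini < 2 µm,
  normal 2–6 µm, giant > 6 µm), GC types
  (type 1: contains a giant chloroplast; type 2: normal chloroplasts but
  no giant; type 3: no chloroplasts), and GC plastid-population morphology
  classes I–IV (WT-like through web-like chlorophyll-less networks).
* **Summaries** — size-class frequency tables, length statistics,
  single-GC type frequencies, chloroplast counts per GC and per GC pair
  (including the joint "cell A : cell B" table), and fold changes between
  genotypes.
* **The random-pairing null** — the core statistic. For `N = 2P` GCs with
  `n_t` cells of type `t`, the observed pair-type counts are compared
  against a uniform random perfect matching of the cells into `P`
  unordered pairs. The null has closed-form expectations

      E[t/t] = n_t (n_t − 1) / (2 (N − 1)),
      E[s/t] = n_s n_t / (N − 1)   (s ≠ t),

  and is also simulated (default 1,000 seeded trials over 100 pairs) to
  obtain null SDs, z-scores and add-one empirical p-values
  `p_enrich = (#{trials ≥ observed} + 1) / (n_trials + 1)` for
  like-with-like pairing preference and hybrid-pair avoidance.
* **A calibrated synthetic generator** — per-genotype population presets
  whose type frequencies, per-GC chloroplast count means, pooled
  size-class mixes and pooled length means are moment-calibrated to the
  published statistics, with a pair-concordance parameter κ (probability
  that both GCs of a stoma inherit one shared type draw) controlling
  like-with-like pairing.

## Worked example

```r
library(gcplastid)

# a synthetic arc6-like population: 100 stomata, seeded
pop <- generate_population("arc6", n_pairs = 100, seed = 42)
gcs <- classify_gcs(pop)
gc_type_frequencies(gcs)[, c("gc_type", "count", "percent")]
#>   gc_type count percent
#> 1 type1      84    42
#> 2 type2      73    36.5
#> 3 type3      43    21.5
res <- pairing_test(gcs, n_trials = 1000, seed = 43)
subset(res$report, pair_type == "type3/type3")
#>   pair_type   actual sim_mean sim_sd     z z_defined p_enrich p_deplete expected
#> 1 type3/type3     10     4.51   1.70  3.22 TRUE       0.00400     0.999     4.54
```

Read: 43 of 200 single GCs are chloroplast-free (type 3). Were the 200
cells paired at random, about 4.5 type3/type3 pairs would be expected
among the 100 stomata — but 10 are observed (z ≈ 3.2, empirical
enrichment p = 0.004), the like-with-like pairing signature that positive
pair concordance (here κ = 0.5) produces.

The `analysis/` directory stages the full workflow: `01` generates the
four per-genotype populations, `02` writes the descriptive tables, `03`
runs the random-pairing null at study scale (200 GCs, 100 pairs, 1,000
trials) for each mutant's published type counts, and `04` checks the
calibration (type-I error ≈ 5% when κ = 0) and power of the enrichment
test. Each emitted CSV carries a `.meta.json` provenance sidecar with
seed and parameters.

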