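#!/usr/bin/env Rscript

# Stage 3: the random-pairing null at study scale. For each mutant the
# published single-GC type counts among 200 GCs are taken as fixed, the 200
# cells are shuffled into 100 pairs uniformly at random, and pair-type
# counts are averaged over 1,000 trials; the closed-form expectation
# E[t/t] = n_t(n_t-1)/(2(N-1)), E[s/t] = n_s n_t/(N-1) is reported
# alongside. The published pair-level counts themselves are not deposited,
# so the observed-vs-null comparison is then demonstrated on synthetic
# concordant populations (kappa = 0.5), where like-with-like pairing is
# built in.

suppressPackageStartupMessages({
  library(gcplastid)
  library(dplyr)
})

out_dir <- "results"
seed <- 20260300

# published type counts among 200 GCs; arc5 is printed exactly, the other
# two are rounded from printed percentages and adjusted on the residual
# type-2 slot to total 200
actual_counts <- list(
  arc5 = c(type1 = 10, type2 = 186, type3 = 4),
  arc6 = c(type1 = 86, type2 = 70, type3 = 44),
  atminE1 = c(type1 = 142, type2 = 40, type3 = 18)
)

for (ln in names(actual_counts)) {
  counts <- actual_counts[[ln]]
  sim <- simulate_random_pairing(counts, n_trials = 1000, seed = seed + match(ln, names(actual_counts)))
  out <- sim$summary %>%
    left_join(expected_pair_counts(counts), by = "pair_type")
  path <- file.path(out_dir, paste0("pairing_null_", ln, ".csv"))
  readr::write_csv(out, path)
  write_sidecar(path, line = ln, type_counts = as.list(counts),
                n_trials = sim$n_trials, seed = sim$seed)
  cat(sprintf("\n%s (n = %s): null pair-type counts over 100 pairs\n",
              ln, paste(counts, collapse = "/")))
  print(as.data.frame(out), digits = 3)
}

cat("\n--- preference test on synthetic concordant populations (kappa = 0.5) ---\n")
for (ln in names(actual_counts)) {
  pop <- generate_population(ln, n_pairs = 100, seed = seed + 10 + match(ln, names(actual_counts)))
  res <- pairing_test(classify_gcs(pop), n_trials = 1000,
                      seed = seed + 20 + match(ln, names(actual_counts)))
  path <- file.path(out_dir, paste0("pairing_test_", ln, ".csv"))
  readr::write_csv(res$report, path)
  write_sidecar(path, line = ln, kappa = 0.5, n_pairs = 100,
                n_trials = res$n_trials, seed = res$seed,
                type_counts = as.list(res$type_counts))
  r33 <- res$report %>% filter(pair_type == "type3/type3")
  cat(sprintf(
    "%-8s type3/type3: actual %d vs null %.2f +/- %.2f  (p_enrich = %.3f)\n",
    ln, r33$actual, r33$sim_mean, r33$sim_sd, r33$p_enrich))
}
cat("\nWith positive pair concordance the type3/type3 excess over the null\nis recovered, mirroring the like-with-like pairing seen in the mutants.\n")
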