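#!/usr/bin/env Rscript

# Stage 1: generate one calibrated synthetic guard-cell population per
# genotype line (WT, arc5, arc6, atminE1) and write them in the standard
# plastid CSV schema. These populations stand in for the undeposited
# microscopy measurements in all later stages.

suppressPackageStartupMessages(library(gcplastid))

n_pairs <- 1000
base_seed <- 20260100
out_dir <- "results/populations"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

lines <- c("WT", "arc5", "arc6", "atminE1")
for (i in seq_along(lines)) {
  ln <- lines[i]
  seed <- base_seed + i
  pop <- generate_population(ln, n_pairs = n_pairs, seed = seed)
  path <- file.path(out_dir, paste0(ln, ".csv"))
  write_plastid_table(pop, path)
  params <- attr(pop, "params")
  write_sidecar(path,
                line = ln, n_pairs = n_pairs, seed = seed,
                kappa = params$kappa,
                type_probs = as.list(params$type_probs))
  cat(sprintf("%-8s %5d GC pairs, %6d plastid rows -> %s\n",
              ln, n_pairs, nrow(pop), path))
}
cat("\nEach CSV has a .meta.json sidecar recording line, seed and kappa.\n")
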