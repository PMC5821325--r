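#!/usr/bin/env Rscript

# Stage 2: descriptive summaries of the generated populations — the
# size-class frequency / length-statistics table, single-GC type
# frequencies, and chloroplast-count distributions per GC and per GC pair.

suppressPackageStartupMessages({
  library(gcplastid)
  library(dplyr)
})

out_dir <- "results"
lines <- c("WT", "arc5", "arc6", "atminE1")
pops <- bind_rows(lapply(
  file.path("results/populations", paste0(lines, ".csv")),
  read_plastid_table
))
pops$line <- factor(pops$line, levels = lines)

# Combined size-class frequency and length-statistics summary per line
freq <- size_frequency_table(pops)
len <- length_stats(pops)
sizefreq_wide <- freq %>%
  mutate(cell = sprintf("%d (%.1f%%)", count, percent)) %>%
  select(line, size_class, cell) %>%
  tidyr::pivot_wider(names_from = line, values_from = cell) %>%
  mutate(size_class = as.character(size_class))
moments <- len %>%
  mutate(`mean_sd` = sprintf("%.1f +/- %.1f", mean, sd),
         max = sprintf("%.1f", max), min = sprintf("%.1f", min),
         n = as.character(n)) %>%
  select(line, mean_sd, max, min, n) %>%
  tidyr::pivot_longer(-line, names_to = "size_class") %>%
  tidyr::pivot_wider(names_from = line)
readr::write_csv(bind_rows(sizefreq_wide, moments), file.path(out_dir, "size_class_summary.csv"))
write_sidecar(file.path(out_dir, "size_class_summary.csv"),
              inputs = as.list(paste0("results/populations/", lines, ".csv")))

cat("Chloroplast length by line (um):\n")
print(as.data.frame(len), digits = 3)

# Single-GC type frequencies
gcs <- classify_gcs(pops)
f <- gc_type_frequencies(gcs)
readr::write_csv(f, file.path(out_dir, "gc_type_frequencies.csv"))
cat("\nGC type frequencies (%):\n")
print(as.data.frame(tidyr::pivot_wider(
  f %>% mutate(percent = round(percent, 1)) %>% select(line, gc_type, percent),
  names_from = gc_type, values_from = percent)))

t1 <- f %>% filter(gc_type == "type1")
cat(sprintf(
  "\nType-1 GCs are %.1f-fold more frequent in atminE1 than in arc6.\n",
  fold_change(t1$percent[t1$line == "atminE1"], t1$percent[t1$line == "arc6"])))

# Chloroplast counts per GC and per pair
for (ln in lines) {
  cd <- count_distribution(pops[pops$line == ln, ])
  readr::write_csv(cd$joint, file.path(out_dir, paste0("joint_counts_", ln, ".csv")))
  top <- cd$joint[which.max(cd$joint$n_pairs), ]
  cat(sprintf(
    "%-8s %.1f +/- %.1f chloroplasts per GC (max %d, min %d); modal pair %d:%d\n",
    ln, cd$gc_stats$mean, cd$gc_stats$sd, cd$gc_stats$max, cd$gc_stats$min,
    top$count_a, top$count_b))
}
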