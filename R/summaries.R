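# Descriptive summaries: size-class frequency tables, length statistics,
# GC-type frequencies, chloroplast-count distributions, fold changes.

filter_chloroplasts <- function(plastids, chloroplasts_only) {
  if (chloroplasts_only) {
    plastids[is_chloroplast(plastids$chlorophyllous), , drop = FALSE]
  } else {
    plastids
  }
}

#' Size-class frequency table
#'
#' Counts and percentages of chloroplasts falling into each size class
#' (mini / normal / giant), per genotype line. Chlorophyll-less plastids are
#' excluded by default: the published frequency table is a table of
#' chloroplasts. Percentages are exact (`100 * count / total`); round at
#' presentation time if one-decimal display is wanted.
#'
#' @param plastids Tidy plastid table (see [read_plastid_table()]).
#' @param chloroplasts_only Restrict to chlorophyllous plastids (default);
#'   set `FALSE` for a parallel all-plastid summary.
#' @return Tibble with columns `line`, `size_class`, `count`, `percent`,
#'   `total`; counts sum to `total` within each line.
#' @export
size_frequency_table <- function(plastids, chloroplasts_only = TRUE) {
  lines <- unique(plastids$line)
  x <- filter_chloroplasts(plastids, chloroplasts_only)
  empty <- setdiff(lines, unique(x$line))
  if (length(empty) > 0) {
    warn(paste0("line(s) with zero chloroplasts, reporting zeros: ",
                paste(empty, collapse = ", ")))
  }
  base <- tidyr::expand_grid(
    line = lines,
    size_class = factor(size_classes(), levels = size_classes())
  )
  tallied <- x %>%
    mutate(size_class = classify_size(.data$length_um)) %>%
    count(.data$line, .data$size_class, name = "count")
  base %>%
    left_join(tallied, by = c("line", "size_class")) %>%
    mutate(count = ifelse(is.na(.data$count), 0L, .data$count)) %>%
    group_by(.data$line) %>%
    mutate(
      total = sum(.data$count),
      percent = ifelse(.data$total > 0, 100 * .data$count / .data$total, 0)
    ) %>%
    ungroup() %>%
    select("line", "size_class", "count", "percent", "total")
}

#' Chloroplast length statistics
#'
#' Arithmetic mean, sample SD (n - 1 denominator), maximum, minimum and n of
#' chloroplast body lengths, per line.
#'
#' @inheritParams size_frequency_table
#' @return Tibble with columns `line`, `n`, `mean`, `sd`, `max`, `min`.
#' @export
length_stats <- function(plastids, chloroplasts_only = TRUE) {
  x <- filter_chloroplasts(plastids, chloroplasts_only)
  if (nrow(x) == 0) abort("no chloroplasts to summarise.")
  x %>%
    group_by(.data$line) %>%
    summarise(
      n = n(),
      mean = mean(.data$length_um),
      sd = sd(.data$length_um),
      max = max(.data$length_um),
      min = min(.data$length_um),
      .groups = "drop"
    )
}

#' Guard-cell type frequencies in single GCs
#'
#' @param gcs Classified GC tibble (from [classify_gcs()]).
#' @param types Type labels to tabulate over.
#' @return Tibble with columns `line`, `gc_type`, `count`, `percent`,
#'   `n_gcs`.
#' @export
gc_type_frequencies <- function(gcs, types = c("type1", "type2", "type3")) {
  if (nrow(gcs) == 0) abort("no GCs to summarise.")
  extra <- setdiff(unique(as.character(gcs$gc_type)), types)
  if (length(extra) > 0) {
    abort(paste0("GC types outside the admitted set: ", paste(extra, collapse = ", ")))
  }
  tidyr::expand_grid(line = unique(gcs$line),
                     gc_type = factor(types, levels = types)) %>%
    left_join(
      gcs %>%
        mutate(gc_type = factor(as.character(.data$gc_type), levels = types)) %>%
        count(.data$line, .data$gc_type, name = "count"),
      by = c("line", "gc_type")
    ) %>%
    mutate(count = ifelse(is.na(.data$count), 0L, .data$count)) %>%
    group_by(.data$line) %>%
    mutate(n_gcs = sum(.data$count),
           percent = 100 * .data$count / .data$n_gcs) %>%
    ungroup() %>%
    select("line", "gc_type", "count", "percent", "n_gcs")
}

#' Chloroplast-count distribution per GC and per GC pair
#'
#' Counts chloroplasts in every GC (a GC whose plastids are all
#' chlorophyll-less counts zero), summarises per-GC and per-stoma counts,
#' and builds the symmetric joint table of (cell A, cell B) counts. The A/B
#' assignment within a stoma is arbitrary, so each pair contributes to both
#' orientations and the joint table equals its transpose by construction;
#' diagonal cells hold one entry per concordant pair, off-diagonal cells
#' mirror each other.
#'
#' @param plastids Tidy plastid table.
#' @return List of class `count_distribution`: `per_gc` (line, stoma_id,
#'   gc_id, n_chloroplasts), `gc_stats` and `stoma_stats` (per-line mean,
#'   sd, max, min), and `joint` (line, count_a, count_b, n_pairs).
#' @export
count_distribution <- function(plastids) {
  per_gc <- plastids %>%
    group_by(.data$line, .data$stoma_id, .data$gc_id) %>%
    summarise(n_chloroplasts = sum(is_chloroplast(.data$chlorophyllous)),
              .groups = "drop")

  count_stats <- function(df, value) {
    df %>%
      group_by(.data$line) %>%
      summarise(
        n = n(),
        mean = mean(.data[[value]]),
        sd = sd(.data[[value]]),
        max = max(.data[[value]]),
        min = min(.data[[value]]),
        .groups = "drop"
      )
  }

  per_stoma <- per_gc %>%
    group_by(.data$line, .data$stoma_id) %>%
    summarise(n_gcs = n(), total = sum(.data$n_chloroplasts), .groups = "drop")
  bad <- per_stoma %>% filter(.data$n_gcs != 2)
  if (nrow(bad) > 0) {
    abort(sprintf("%d stoma(ta) without exactly 2 GCs; pair tables need complete pairs.",
                  nrow(bad)))
  }

  wide <- per_gc %>%
    arrange(.data$line, .data$stoma_id, .data$gc_id) %>%
    group_by(.data$line, .data$stoma_id) %>%
    summarise(a = .data$n_chloroplasts[1], b = .data$n_chloroplasts[2],
              .groups = "drop")
  joint <- bind_rows(
    wide %>% select("line", count_a = "a", count_b = "b"),
    wide %>% filter(.data$a != .data$b) %>%
      select("line", count_a = "b", count_b = "a")
  ) %>%
    count(.data$line, .data$count_a, .data$count_b, name = "n_pairs") %>%
    arrange(.data$line, .data$count_a, .data$count_b)

  structure(
    list(
      per_gc = per_gc,
      gc_stats = count_stats(per_gc, "n_chloroplasts"),
      stoma_stats = count_stats(per_stoma, "total"),
      joint = joint
    ),
    class = "count_distribution"
  )
}

#' @export
print.count_distribution <- function(x, ...) {
  cat("Chloroplast counts per GC:\n")
  print(x$gc_stats, ...)
  cat("Chloroplast counts per stoma (GC pair):\n")
  print(x$stoma_stats, ...)
  invisible(x)
}

#' Fold change between two percentage frequencies
#'
#' Ratio `freq_a / freq_b`, reported to one decimal place, as used to
#' compare type frequencies between genotypes (e.g. 71% vs 43% -> 1.7).
#'
#' @param freq_a,freq_b Percentages (or any non-negative frequencies on a
#'   common scale); `freq_b` must be positive.
#' @return The ratio rounded to one decimal.
#' @export
fold_change <- function(freq_a, freq_b) {
  if (!is.numeric(freq_a) || !is.numeric(freq_b)) abort("frequencies must be numeric.")
  if (any(freq_b <= 0)) abort("`freq_b` must be positive.")
  round(freq_a / freq_b, 1)
}
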