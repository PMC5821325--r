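# Pair-level analysis: observed GC-type pair counts, the random-pairing
# Monte-Carlo null, its closed-form expectation, and the preference test.

# Unordered pair labels "s/t" for sorted type names, s <= t in `types` order.
pair_type_labels <- function(types) {
  k <- length(types)
  out <- character(0)
  for (i in seq_len(k)) {
    for (j in i:k) out <- c(out, paste0(types[i], "/", types[j]))
  }
  out
}

# k x k lookup from an (unordered) pair of type indices to the combo index.
pair_lookup <- function(k) {
  m <- matrix(0L, k, k)
  idx <- 0L
  for (i in seq_len(k)) {
    for (j in i:k) {
      idx <- idx + 1L
      m[i, j] <- idx
      m[j, i] <- idx
    }
  }
  m
}

check_type_counts <- function(type_counts) {
  if (is.null(names(type_counts)) || any(!nzchar(names(type_counts)))) {
    abort("`type_counts` must be a named vector of non-negative integers.")
  }
  if (any(type_counts < 0) || any(type_counts != round(type_counts))) {
    abort("`type_counts` must be non-negative integers.")
  }
  n <- sum(type_counts)
  if (n %% 2 != 0) {
    abort(sprintf("total number of GCs must be even to form pairs (got %d).", n))
  }
  type_counts
}

#' Tally guard-cell types
#'
#' @param gcs Classified GC tibble (from [classify_gcs()]) or a factor /
#'   character vector of types.
#' @param types Type labels admitted into the tally; the random-pairing null
#'   is defined over the three in-taxonomy types.
#' @return Named integer vector of per-type counts, in `types` order.
#' @export
gc_type_counts <- function(gcs, types = c("type1", "type2", "type3")) {
  tv <- if (is.data.frame(gcs)) gcs$gc_type else gcs
  tv <- as.character(tv)
  extra <- setdiff(unique(tv), types)
  if (length(extra) > 0) {
    abort(paste0("GC types outside the admitted set: ", paste(extra, collapse = ", ")))
  }
  counts <- table(factor(tv, levels = types))
  setNames(as.integer(counts), types)
}

#' Count unordered GC-type pair combinations across stomata
#'
#' Each stoma contributes one unordered pair of GC types; with the three
#' in-taxonomy types the six combinations are 1/1, 1/2, 1/3, 2/2, 2/3, 3/3.
#' The count is invariant to within-pair ordering.
#'
#' @param gcs Tibble with columns `stoma_id` and `gc_type` (two rows per
#'   stoma), e.g. the output of [classify_gcs()].
#' @param types Admissible type labels, in display order.
#' @param permissive If `TRUE`, stomata with a GC outside `types` or without
#'   exactly two GCs are dropped with a warning instead of erroring.
#' @return Tibble with columns `pair_type` (factor over all combinations)
#'   and `count`; counts sum to the number of stomata used.
#' @export
count_pair_types <- function(gcs, types = c("type1", "type2", "type3"),
                             permissive = FALSE) {
  if (!all(c("stoma_id", "gc_type") %in% names(gcs))) {
    abort("`gcs` must have columns `stoma_id` and `gc_type`.")
  }
  tv <- as.character(gcs$gc_type)
  sid <- as.character(gcs$stoma_id)

  bad_type <- !(tv %in% types)
  sizes <- table(sid)
  bad_stoma <- union(unique(sid[bad_type]), names(sizes)[sizes != 2])
  if (length(bad_stoma) > 0) {
    msg <- sprintf(
      "%d stoma(ta) with out-of-taxonomy GCs or != 2 GCs: %s",
      length(bad_stoma), paste(head(bad_stoma, 5), collapse = ", ")
    )
    if (!permissive) abort(msg)
    warn(paste0("dropping ", msg))
    keep <- !(sid %in% bad_stoma)
    tv <- tv[keep]
    sid <- sid[keep]
  }

  labels <- pair_type_labels(types)
  if (length(sid) == 0) {
    return(tibble(pair_type = factor(labels, levels = labels), count = 0L))
  }
  ord <- order(sid, match(tv, types))
  tv <- tv[ord]
  sid <- sid[ord]
  a <- tv[c(TRUE, FALSE)]
  b <- tv[c(FALSE, TRUE)]
  key <- paste0(a, "/", b)
  counts <- table(factor(key, levels = labels))
  tibble(pair_type = factor(labels, levels = labels),
         count = as.integer(counts))
}

#' Expected pair-type counts under uniform random pairing
#'
#' For `N = 2P` guard cells of which `n_t` carry type `t`, a uniform random
#' perfect matching into `P` unordered pairs gives
#' `E[t/t] = n_t (n_t - 1) / (2 (N - 1))` and, for `s != t`,
#' `E[s/t] = n_s n_t / (N - 1)`. The expectations sum to `P`. This is the
#' closed-form oracle for [simulate_random_pairing()].
#'
#' @param type_counts Named vector of non-negative integer per-type counts;
#'   the total must be even.
#' @return Tibble with columns `pair_type` and `expected`.
#' @examples
#' expected_pair_counts(c(A = 2, B = 2)) # 1/3, 4/3, 1/3
#' @export
expected_pair_counts <- function(type_counts) {
  type_counts <- check_type_counts(type_counts)
  types <- names(type_counts)
  n <- sum(type_counts)
  if (n < 2) abort("need at least one pair (N >= 2).")
  labels <- pair_type_labels(types)
  expected <- numeric(length(labels))
  idx <- 0L
  k <- length(types)
  for (i in seq_len(k)) {
    for (j in i:k) {
      idx <- idx + 1L
      expected[idx] <- if (i == j) {
        type_counts[i] * (type_counts[i] - 1) / (2 * (n - 1))
      } else {
        type_counts[i] * type_counts[j] / (n - 1)
      }
    }
  }
  tibble(pair_type = factor(labels, levels = labels), expected = expected)
}

#' Simulate the random-pairing null
#'
#' Each trial shuffles the `N` labelled GCs uniformly at random and pairs
#' consecutive elements — a uniform random perfect matching into `N/2`
#' unordered pairs with the per-type counts held fixed at their observed
#' values — then counts each pair-type combination. Means and SDs are taken
#' across trials. The default 1,000 trials over 100 pairs mirror the scale
#' of the published resampling analysis.
#'
#' @inheritParams expected_pair_counts
#' @param n_trials Number of Monte-Carlo trials (>= 1).
#' @param seed Integer seed; recorded in the result. The simulation is
#'   bit-reproducible given `seed`, and the caller's RNG state is left
#'   untouched.
#' @return Object of class `pairing_sim`: a list with `summary` (tibble of
#'   `pair_type`, `sim_mean`, `sim_sd`), `trials` (an `n_trials` x
#'   pair-type integer matrix), `type_counts`, `n_pairs`, `n_trials`,
#'   `seed`.
#' @export
simulate_random_pairing <- function(type_counts, n_trials = 1000, seed) {
  type_counts <- check_type_counts(type_counts)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1) {
    abort("`seed` must be a single integer (recorded in the result).")
  }
  if (n_trials < 1) abort("`n_trials` must be >= 1.")
  types <- names(type_counts)
  k <- length(types)
  n <- sum(type_counts)
  if (n < 2) abort("need at least one pair (N >= 2).")
  n_pairs <- n %/% 2L
  labels <- pair_type_labels(types)
  lookup <- pair_lookup(k)
  labs <- rep(seq_len(k), type_counts)
  ncomb <- length(labels)
  odd <- c(TRUE, FALSE)
  even <- c(FALSE, TRUE)

  trials <- matrix(0L, nrow = n_trials, ncol = ncomb,
                   dimnames = list(NULL, labels))
  withr::with_seed(as.integer(seed), {
    for (t in seq_len(n_trials)) {
      s <- labs[sample.int(n)]
      a <- s[odd]
      b <- s[even]
      trials[t, ] <- tabulate(lookup[(a - 1L) * k + b], nbins = ncomb)
    }
  })

  structure(
    list(
      summary = tibble(
        pair_type = factor(labels, levels = labels),
        sim_mean = unname(colMeans(trials)),
        sim_sd = unname(apply(trials, 2, sd))
      ),
      trials = trials,
      type_counts = type_counts,
      n_pairs = n_pairs,
      n_trials = as.integer(n_trials),
      seed = as.integer(seed)
    ),
    class = "pairing_sim"
  )
}

#' @export
print.pairing_sim <- function(x, ...) {
  cat(sprintf(
    "Random-pairing null: %d GCs (%s) -> %d pairs, %d trials, seed %d\n",
    sum(x$type_counts),
    paste(sprintf("%s=%d", names(x$type_counts), x$type_counts), collapse = ", "),
    x$n_pairs, x$n_trials, x$seed
  ))
  print(x$summary, ...)
  invisible(x)
}

#' Test observed pair-type counts against the random-pairing null
#'
#' For each pair type reports the z-score `(actual - sim_mean) / sim_sd`
#' (`NA`, flagged in `z_defined`, when the null SD is zero) and add-one
#' empirical p-values: `p_enrich = (#\{trials >= actual\} + 1) / (n_trials
#' + 1)` for an excess of that pair type, `p_deplete` analogously with
#' `<=`. No multiple-testing correction is applied; raw per-type values
#' are reported.
#'
#' @param actual Observed pair-type counts: the tibble from
#'   [count_pair_types()] or a named vector over the same pair types.
#' @param sim A `pairing_sim` from [simulate_random_pairing()] computed
#'   from the same GC population (totals must agree).
#' @return Tibble with columns `pair_type`, `actual`, `sim_mean`, `sim_sd`,
#'   `z`, `z_defined`, `p_enrich`, `p_deplete`.
#' @export
pairing_preference_test <- function(actual, sim) {
  if (!inherits(sim, "pairing_sim")) abort("`sim` must come from simulate_random_pairing().")
  labels <- levels(sim$summary$pair_type)
  if (is.data.frame(actual)) {
    av <- setNames(actual$count, as.character(actual$pair_type))
  } else {
    av <- actual
  }
  if (!setequal(names(av), labels)) {
    abort("`actual` and `sim` cover different pair types.")
  }
  av <- av[labels]
  if (sum(av) != sim$n_pairs) {
    abort(sprintf("actual counts sum to %d but the null was built for %d pairs.",
                  sum(av), sim$n_pairs))
  }
  sim_mean <- sim$summary$sim_mean
  sim_sd <- sim$summary$sim_sd
  z <- unname(ifelse(sim_sd > 0, (av - sim_mean) / sim_sd, NA_real_))
  ge <- unname(colSums(sweep(sim$trials, 2, av, ">=") * 1L))
  le <- unname(colSums(sweep(sim$trials, 2, av, "<=") * 1L))
  tibble(
    pair_type = factor(labels, levels = labels),
    actual = as.integer(av),
    sim_mean = sim_mean,
    sim_sd = sim_sd,
    z = z,
    z_defined = sim_sd > 0,
    p_enrich = (ge + 1) / (sim$n_trials + 1),
    p_deplete = (le + 1) / (sim$n_trials + 1)
  )
}

#' Full pairing analysis of a classified GC table
#'
#' Convenience wrapper running the whole pair-level analysis: observed
#' pair-type counts, the Monte-Carlo null, the closed-form expectation and
#' the preference test.
#'
#' @param gcs Classified GC tibble with `stoma_id` and `gc_type`
#'   (two rows per stoma, types 1-3 only).
#' @inheritParams simulate_random_pairing
#' @inheritParams count_pair_types
#' @return List of class `pairing_test` with elements `report` (the
#'   preference-test tibble plus an `expected` column), `sim`,
#'   `type_counts`, `n_trials`, `seed`.
#' @export
pairing_test <- function(gcs, n_trials = 1000, seed, permissive = FALSE) {
  actual <- count_pair_types(gcs, permissive = permissive)
  used <- rep(as.character(actual$pair_type), actual$count)
  type_counts <- gc_type_counts(unlist(strsplit(used, "/", fixed = TRUE)))
  sim <- simulate_random_pairing(type_counts, n_trials = n_trials, seed = seed)
  report <- pairing_preference_test(actual, sim) %>%
    left_join(expected_pair_counts(type_counts), by = "pair_type")
  structure(
    list(report = report, sim = sim, type_counts = type_counts,
         n_trials = sim$n_trials, seed = sim$seed),
    class = "pairing_test"
  )
}

#' @export
print.pairing_test <- function(x, ...) {
  cat(sprintf("Pairing preference test (%d pairs, %d trials, seed %d)\n",
              x$sim$n_pairs, x$n_trials, x$seed))
  print(x$report, ...)
  invisible(x)
}
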