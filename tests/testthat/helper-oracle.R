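# Independent brute-force oracle for the random-pairing null: exhaustive
# enumeration of all perfect matchings of a small labelled population.
# Deliberately shares no code with simulate_random_pairing().

# All perfect matchings of indices 1..n (n even), each a 2-column matrix.
enumerate_matchings <- function(n) {
  rec <- function(idx) {
    if (length(idx) == 0) {
      return(list(matrix(integer(0), nrow = 0, ncol = 2)))
    }
    first <- idx[1]
    rest <- idx[-1]
    out <- list()
    for (j in seq_along(rest)) {
      for (m in rec(rest[-j])) {
        out[[length(out) + 1]] <- rbind(c(first, rest[j]), m)
      }
    }
    out
  }
  rec(seq_len(n))
}

# Per-matching pair-type counts for a named type-count vector; rows are the
# (equiprobable) matchings, columns the unordered pair labels "s/t".
enum_pair_count_matrix <- function(type_counts) {
  types <- names(type_counts)
  k <- length(types)
  labels <- character(0)
  for (i in seq_len(k)) {
    for (j in i:k) labels <- c(labels, paste0(types[i], "/", types[j]))
  }
  labs <- rep(seq_len(k), type_counts)
  matchings <- enumerate_matchings(sum(type_counts))
  counts <- t(vapply(matchings, function(m) {
    a <- pmin(labs[m[, 1]], labs[m[, 2]])
    b <- pmax(labs[m[, 1]], labs[m[, 2]])
    key <- paste0(types[a], "/", types[b])
    as.integer(table(factor(key, levels = labels)))
  }, integer(length(labels))))
  colnames(counts) <- labels
  counts
}

enum_expected_counts <- function(type_counts) {
  colMeans(enum_pair_count_matrix(type_counts))
}

# Small helper to build a one-line plastid tibble from per-class chloroplast
# counts, using representative in-class lengths.
make_class_counts <- function(line, giant = 0, normal = 0, mini = 0,
                              giant_len = 7, normal_len = 4.3, mini_len = 1.5) {
  lens <- c(rep(giant_len, giant), rep(normal_len, normal), rep(mini_len, mini))
  n <- length(lens)
  tibble::tibble(
    line = line,
    stoma_id = rep(sprintf("s%03d", seq_len(ceiling(n / 10))), each = 10)[seq_len(n)],
    gc_id = paste0(rep(sprintf("s%03d", seq_len(ceiling(n / 10))), each = 10)[seq_len(n)], "_a"),
    plastid_id = sprintf("%s_p%04d", line, seq_len(n)),
    length_um = lens,
    chlorophyllous = TRUE,
    reticulate = FALSE
  )
}

# A tiny valid two-stoma plastid table used by the io tests.
make_fixture_table <- function() {
  tibble::tibble(
    line = "WT",
    stoma_id = rep(c("s1", "s2"), each = 4),
    gc_id = rep(c("s1_a", "s1_b", "s2_a", "s2_b"), each = 2),
    plastid_id = sprintf("p%02d", 1:8),
    length_um = c(4.1, 4.9, 5.2, 3.8, 4.5, 6.8, 1.5, 4.0),
    chlorophyllous = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    reticulate = FALSE
  )
}
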