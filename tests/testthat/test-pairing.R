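make_gc_table <- function(pair_types) {
  # pair_types: list of length-2 character vectors, one per stoma
  tibble::tibble(
    stoma_id = rep(sprintf("s%03d", seq_along(pair_types)), each = 2),
    gc_type = unlist(pair_types)
  )
}

test_that("pair-type counting is exact and invariant to within-pair order", {
  gcs <- make_gc_table(list(c("type3", "type3"), c("type1", "type2")))
  out <- count_pair_types(gcs)
  counts <- setNames(out$count, as.character(out$pair_type))
  expect_identical(counts[["type3/type3"]], 1L)
  expect_identical(counts[["type1/type2"]], 1L)
  expect_identical(sum(out$count), 2L)

  swapped <- make_gc_table(list(c("type3", "type3"), c("type2", "type1")))
  expect_identical(count_pair_types(swapped), out)

  many <- make_gc_table(rep(list(c("type2", "type2")), 100))
  out2 <- count_pair_types(many)
  expect_identical(out2$count[out2$pair_type == "type2/type2"], 100L)
  expect_identical(sum(out2$count), 100L)
})

test_that("out-of-taxonomy GCs and incomplete stomata block pair counting unless permissive", {
  gcs <- make_gc_table(list(c("type1", "mini_only"), c("type2", "type2")))
  expect_error(count_pair_types(gcs), "out-of-taxonomy")
  expect_warning(out <- count_pair_types(gcs, permissive = TRUE), "dropping")
  expect_identical(sum(out$count), 1L)

  lone <- tibble::tibble(stoma_id = c("s1", "s1", "s2"),
                         gc_type = c("type2", "type2", "type3"))
  expect_error(count_pair_types(lone), "2 GCs")
})

test_that("closed-form pair expectations equal exhaustive enumeration", {
  # worked example: two types, two cells each -> 3 matchings
  ex <- expected_pair_counts(c(A = 2, B = 2))
  expect_equal(setNames(ex$expected, as.character(ex$pair_type)),
               c("A/A" = 1 / 3, "A/B" = 4 / 3, "B/B" = 1 / 3))

  set.seed(5)
  for (rep in 1:8) {
    n <- sample(c(4, 6, 8), 1)
    counts <- as.integer(stats::rmultinom(1, n, prob = c(0.4, 0.4, 0.2)))
    names(counts) <- c("t1", "t2", "t3")
    ex <- expected_pair_counts(counts)
    oracle <- enum_expected_counts(counts)
    expect_equal(setNames(ex$expected, as.character(ex$pair_type)),
                 oracle, tolerance = 1e-12)
    expect_equal(sum(ex$expected), n / 2)
  }
})

test_that("arc5 type counts give the frozen closed-form expectations", {
  ex <- expected_pair_counts(c(type1 = 10, type2 = 186, type3 = 4))
  v <- setNames(ex$expected, as.character(ex$pair_type))
  expect_equal(v[["type1/type3"]], 40 / 199)
  expect_equal(v[["type3/type3"]], 12 / 398)
  expect_equal(v[["type1/type1"]], 10 * 9 / (2 * 199))
  expect_equal(sum(v), 100)
})

test_that("degenerate expectation cases behave", {
  ex <- expected_pair_counts(c(A = 4))
  expect_equal(ex$expected, 2)
  expect_error(expected_pair_counts(c(A = 3)), "even")
  expect_error(expected_pair_counts(c(2, 2)), "named")
})

test_that("the pairing simulation is seed-deterministic and conservative", {
  counts <- c(type1 = 6, type2 = 10, type3 = 4)
  s1 <- simulate_random_pairing(counts, n_trials = 200, seed = 99)
  s2 <- simulate_random_pairing(counts, n_trials = 200, seed = 99)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$summary, s2$summary)

  # every trial uses each GC exactly once: pair counts sum to P and
  # 2 * n(t/t) + sum_{s != t} n(s/t) recovers each type count
  expect_true(all(rowSums(s1$trials) == s1$n_pairs))
  for (t in names(counts)) {
    same <- paste0(t, "/", t)
    cross <- setdiff(grep(t, colnames(s1$trials), value = TRUE, fixed = TRUE), same)
    recovered <- 2 * s1$trials[, same] + rowSums(s1$trials[, cross, drop = FALSE])
    expect_true(all(recovered == counts[[t]]))
  }
})

test_that("simulated means converge to the enumeration mean", {
  s <- simulate_random_pairing(c(A = 2, B = 2), n_trials = 10000, seed = 12)
  mc_se <- s$summary$sim_sd / sqrt(s$n_trials)
  expect_true(all(abs(s$summary$sim_mean - c(1 / 3, 4 / 3, 1 / 3)) <=
                    3 * mc_se + 1e-9))

  single <- simulate_random_pairing(c(A = 4), n_trials = 50, seed = 3)
  expect_true(all(single$trials == 2L))
  expect_equal(single$summary$sim_sd, 0)
})

test_that("the simulation leaves the caller's RNG state untouched", {
  set.seed(1234)
  before <- .Random.seed
  invisible(simulate_random_pairing(c(A = 2, B = 2), n_trials = 10, seed = 8))
  expect_identical(.Random.seed, before)
})

test_that("preference test reports z and add-one empirical p-values", {
  counts <- c(A = 2, B = 2)
  sim <- simulate_random_pairing(counts, n_trials = 3000, seed = 77)
  actual <- c("A/A" = 1L, "A/B" = 0L, "B/B" = 1L)
  res <- pairing_preference_test(actual, sim)

  # P(A/B = 0) = 1/3 under the 3-matching enumeration
  expect_equal(res$p_deplete[res$pair_type == "A/B"], 1 / 3, tolerance = 0.08)
  # identity tying the two one-sided add-one p-values together
  eq <- unname(colSums(sweep(sim$trials, 2, actual[colnames(sim$trials)], "==") * 1L))
  expect_equal(res$p_enrich + res$p_deplete,
               (sim$n_trials + eq + 2) / (sim$n_trials + 1))
  expect_true(all(res$p_enrich > 0 & res$p_enrich <= 1))

  expect_error(
    pairing_preference_test(c("A/A" = 2L, "A/B" = 0L, "B/B" = 1L), sim),
    "sum")
})

test_that("a zero-variance null flags z as undefined but still returns p-values", {
  sim <- simulate_random_pairing(c(A = 4), n_trials = 100, seed = 2)
  res <- pairing_preference_test(c("A/A" = 2L), sim)
  expect_false(res$z_defined)
  expect_true(is.na(res$z))
  expect_equal(res$p_enrich, 1)
  expect_equal(res$p_deplete, 1)
})

test_that("relabelling types permutes the analysis consistently", {
  counts <- c(x = 4, y = 6)
  ex <- expected_pair_counts(counts)
  ex_swap <- expected_pair_counts(c(y = 6, x = 4))
  v <- setNames(ex$expected, as.character(ex$pair_type))
  w <- setNames(ex_swap$expected, as.character(ex_swap$pair_type))
  expect_equal(v[["x/x"]], w[["x/x"]])
  expect_equal(v[["x/y"]], w[["y/x"]])
  expect_equal(v[["y/y"]], w[["y/y"]])
})

test_that("pairing_test runs the whole pair-level analysis end to end", {
  gcs <- make_gc_table(c(
    rep(list(c("type3", "type3")), 6),
    rep(list(c("type2", "type2")), 40),
    rep(list(c("type1", "type2")), 4)
  ))
  res <- pairing_test(gcs, n_trials = 500, seed = 41)
  expect_s3_class(res, "pairing_test")
  expect_identical(res$type_counts, c(type1 = 4L, type2 = 84L, type3 = 12L))
  expect_equal(sum(res$report$actual), 50)
  expect_equal(sum(res$report$expected), 50)
  # the deliberately concordant type-3 pairs are enriched
  p33 <- res$report$p_enrich[res$report$pair_type == "type3/type3"]
  expect_lt(p33, 0.05)
})
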