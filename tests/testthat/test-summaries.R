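test_that("size-class frequency tables reproduce published worked examples", {
  # arc6 column: 64 giant and 102 normal chloroplasts of 200; the printed
  # 17.0% mini implies 34 mini cells (the printed count of 35 would make
  # the column sum to 201); percentages are computed exactly, not copied
  arc6 <- make_class_counts("arc6", giant = 64, normal = 102, mini = 34)
  tab <- size_frequency_table(arc6)
  pct <- setNames(tab$percent, as.character(tab$size_class))
  expect_equal(pct[["giant"]], 32.0)
  expect_equal(pct[["normal"]], 51.0)
  expect_equal(pct[["mini"]], 17.0)
  expect_identical(unique(tab$total), 200L)
  expect_equal(sum(tab$count), 200)
  expect_equal(sum(tab$percent), 100)
})

test_that("degenerate size tables behave", {
  one <- make_class_counts("x", normal = 1, normal_len = 4)
  tab <- size_frequency_table(one)
  expect_equal(tab$count, c(0, 1, 0))
  expect_equal(tab$percent, c(0, 100, 0))

  giants <- make_class_counts("g", giant = 10)
  tab <- size_frequency_table(giants)
  expect_equal(tab$percent, c(0, 0, 100))
})

test_that("chlorophyll-less plastids are excluded unless asked for", {
  x <- make_class_counts("m", normal = 4)
  extra <- x[1:2, ]
  extra$plastid_id <- c("ng1", "ng2")
  extra$length_um <- c(1.2, 1.4)
  extra$chlorophyllous <- FALSE
  both <- dplyr::bind_rows(x, extra)
  tab <- size_frequency_table(both)
  expect_identical(unique(tab$total), 4L)
  tab_all <- size_frequency_table(both, chloroplasts_only = FALSE)
  expect_identical(unique(tab_all$total), 6L)
  expect_equal(tab_all$count[tab_all$size_class == "mini"], 2)
})

test_that("a line with zero chloroplasts yields zeros with a warning", {
  x <- make_class_counts("empty", normal = 3)
  x$chlorophyllous <- FALSE
  expect_warning(tab <- size_frequency_table(x), "zero chloroplasts")
  expect_equal(tab$count, c(0, 0, 0))
  expect_equal(tab$percent, c(0, 0, 0))
})

test_that("length statistics use the sample SD and agree with the size table on n", {
  x <- make_class_counts("a", normal = 3, normal_len = 4)
  st <- length_stats(x)
  expect_equal(st[, c("mean", "sd", "max", "min")],
               tibble::tibble(mean = 4, sd = 0, max = 4, min = 4))

  y <- make_class_counts("b", normal = 2)
  y$length_um <- c(2, 6)
  st <- length_stats(y)
  expect_equal(st$mean, 4)
  expect_equal(st$max, 6)
  expect_equal(st$min, 2)
  expect_equal(st$sd, sd(c(2, 6)))

  tab <- size_frequency_table(y)
  expect_identical(unique(tab$total), st$n)

  y$chlorophyllous <- FALSE
  expect_error(length_stats(y), "no chloroplasts")
})

test_that("WT generator output recovers the published length moments", {
  pop <- generate_population("WT", n_pairs = 300, seed = 17)
  st <- length_stats(pop)
  expect_lt(abs(st$mean - 4.3), 3 * st$sd / sqrt(st$n))
  expect_lt(abs(st$sd - 0.8), 0.1)
})

test_that("GC type frequencies reproduce the arc5 single-cell percentages", {
  gcs <- tibble::tibble(
    line = "arc5",
    gc_type = rep(c("type1", "type2", "type3"), c(10, 186, 4))
  )
  f <- gc_type_frequencies(gcs)
  expect_equal(setNames(f$percent, as.character(f$gc_type)),
               c(type1 = 5, type2 = 93, type3 = 2))
  expect_identical(unique(f$n_gcs), 200L)

  all2 <- tibble::tibble(line = "x", gc_type = rep("type2", 8))
  f2 <- gc_type_frequencies(all2)
  expect_equal(setNames(f2$percent, as.character(f2$gc_type)),
               c(type1 = 0, type2 = 100, type3 = 0))

  expect_error(gc_type_frequencies(all2[0, ]), "no GCs")
  expect_error(
    gc_type_frequencies(tibble::tibble(line = "x", gc_type = "mini_only")),
    "outside")
})

make_pair_pop <- function(counts_a, counts_b, line = "WT") {
  # one stoma per element; GC counts realised as normal-sized chloroplasts
  rows <- list()
  for (i in seq_along(counts_a)) {
    sid <- sprintf("s%03d", i)
    for (side in c("a", "b")) {
      m <- if (side == "a") counts_a[i] else counts_b[i]
      gc_id <- paste0(sid, "_", side)
      # a chloroplast-free GC still holds a chlorophyll-less plastid
      k <- max(m, 1)
      rows[[length(rows) + 1]] <- tibble::tibble(
        line = line, stoma_id = sid, gc_id = gc_id,
        plastid_id = sprintf("%s_p%02d", gc_id, seq_len(k)),
        length_um = if (m > 0) rep(4.5, m) else 1.5,
        chlorophyllous = m > 0,
        reticulate = FALSE
      )
    }
  }
  dplyr::bind_rows(rows)
}

test_that("count distributions summarise GCs, stomata and the joint pair table", {
  pop <- make_pair_pop(rep(4, 30), rep(5, 30))
  cd <- count_distribution(pop)
  expect_equal(cd$gc_stats$mean, 4.5)
  expect_equal(cd$stoma_stats$mean, 9)
  # per-stoma mean is twice the per-GC mean on the same data
  expect_equal(cd$stoma_stats$mean, 2 * cd$gc_stats$mean)
  top <- cd$joint[which.max(cd$joint$n_pairs), ]
  expect_setequal(c(top$count_a, top$count_b), c(4, 5))

  single <- make_pair_pop(0, 3)
  cd1 <- count_distribution(single)
  expect_equal(cd1$stoma_stats$mean, 3)
  expect_equal(cd1$gc_stats$min, 0)
})

test_that("the joint pair table is symmetric under A/B relabelling", {
  set.seed(9)
  pop <- make_pair_pop(sample(3:7, 40, replace = TRUE),
                       sample(3:7, 40, replace = TRUE))
  cd <- count_distribution(pop)
  j <- cd$joint
  transposed <- j[, c("line", "count_b", "count_a", "n_pairs")]
  names(transposed) <- names(j)
  expect_equal(dplyr::arrange(j, count_a, count_b),
               dplyr::arrange(transposed, count_a, count_b))
})

test_that("incomplete stomata block the pair-level count table", {
  pop <- make_pair_pop(4, 5)
  expect_error(count_distribution(pop[pop$gc_id == "s001_a", ]), "2 GCs")
})

test_that("fold changes reproduce the published type-1 comparison", {
  expect_equal(fold_change(71, 43), 1.7)
  expect_equal(fold_change(50, 50), 1.0)
  expect_equal(fold_change(30, 10), 3.0)
  expect_error(fold_change(10, 0), "positive")
})
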