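# Synthetic guard-cell populations calibrated to the published per-genotype
# statistics, so every downstream stage is testable without microscopy data.
#
# The generative model per stoma:
#   * with probability kappa one GC type is drawn from `type_probs` and
#     shared by both GCs; otherwise each GC draws its type independently.
#     The single-GC marginal equals `type_probs` for any kappa.
#   * type-1 GCs hold 1 + Binomial(n-1, extra_giant_prob) giant chloroplasts
#     plus normal/mini chloroplasts; type-2 GCs hold normal/mini chloroplasts
#     with at least one normal; type-3 GCs hold only chlorophyll-less mini
#     plastids (numerous; optionally reticulate, i.e. a web-like class IV
#     structure).
#   * chloroplast counts per GC are rounded clamped normals; lengths are
#     truncated normals per size class. Both are moment-calibrated so the
#     population reproduces, in expectation, the printed type frequencies,
#     per-GC chloroplast count mean, pooled size-class frequencies and
#     pooled length mean of each genotype.

line_targets <- function() {
  list(
    WT = list(
      type_probs = c(type1 = 0.005, type2 = 0.995, type3 = 0),
      count_mean = 5, count_sd = 1, count_lo = 3, count_hi = 7,
      len_mean = 4.3, len_min = 2.9, len_max = 6.8,
      freq = c(giant = 0.005, normal = 0.995, mini = 0),
      giant_len_mean = 6.4, giant_len_sd = 0.3,
      normal_len_sd = 0.8,
      mini_len_mean = 1.5, mini_len_sd = 0.3,
      kappa = 0, reticulate_prob = 0, nongreen_lambda = 0
    ),
    arc5 = list(
      type_probs = c(type1 = 10, type2 = 186, type3 = 4) / 200,
      count_mean = 4, count_sd = 1, count_lo = 1, count_hi = 8,
      len_mean = 4.8, len_min = 1.5, len_max = 10.2,
      freq = c(giant = 0.035, normal = 0.955, mini = 0.01),
      giant_len_mean = 7.3, giant_len_sd = 1.0,
      normal_len_sd = 0.9,
      mini_len_mean = 1.75, mini_len_sd = 0.2,
      kappa = 0.5, reticulate_prob = 0, nongreen_lambda = 0.3
    ),
    arc6 = list(
      type_probs = c(type1 = 43, type2 = 36, type3 = 22) / 101,
      count_mean = 2, count_sd = 2, count_lo = 1, count_hi = 9,
      len_mean = 5.2, len_min = 1.0, len_max = 14.1,
      freq = c(giant = 0.32, normal = 0.51, mini = 0.175),
      giant_len_mean = 8.5, giant_len_sd = 1.8,
      normal_len_sd = 1.0,
      mini_len_mean = 1.5, mini_len_sd = 0.3,
      kappa = 0.5, reticulate_prob = 0.3, nongreen_lambda = 0.8
    ),
    atminE1 = list(
      type_probs = c(type1 = 71, type2 = 21, type3 = 9) / 101,
      count_mean = 3, count_sd = 1, count_lo = 1, count_hi = 8,
      len_mean = 5.3, len_min = 1.5, len_max = 14.5,
      freq = c(giant = 0.275, normal = 0.595, mini = 0.13),
      giant_len_mean = 8.5, giant_len_sd = 1.8,
      normal_len_sd = 1.0,
      mini_len_mean = 1.75, mini_len_sd = 0.2,
      kappa = 0.5, reticulate_prob = 0.3, nongreen_lambda = 0.8
    )
  )
}

#' Preset generative parameters for a genotype line
#'
#' Builds calibrated parameters for one of the four study lines. Calibration
#' solves, in closed form or by root finding, for (i) the location of the
#' rounded clamped-normal chloroplast count whose mean over all GCs
#' (type-3 cells contribute zero) equals the printed per-GC mean, (ii) the
#' extra-giant probability of type-1 GCs reconciling the pooled giant
#' chloroplast fraction with the type-1 GC frequency (capped at 0.6), (iii)
#' the per-small-chloroplast mini probability hitting the pooled mini
#' fraction, and (iv) truncated-normal length locations so the pooled
#' chloroplast length mean equals the printed value given the structural
#' class mix. Printed type-frequency vectors summing to 101% are
#' normalised.
#'
#' @param line One of `"WT"`, `"arc5"`, `"arc6"`, `"atminE1"`.
#' @param kappa Optional override of the pair-concordance probability: with
#'   probability `kappa` both GCs of a stoma share one type draw. The
#'   single-GC marginal is unaffected. No measured value exists; the mutant
#'   presets default to 0.5 (positive concordance), WT to 0.
#' @param reticulate_prob Optional override of the probability that a
#'   type-3 GC carries a web-like (class IV) plastid structure.
#' @return List of class `line_params` holding the type probabilities,
#'   kappa, calibrated count and length components, type-3 composition and
#'   the printed targets used for calibration.
#' @export
default_params <- function(line, kappa = NULL, reticulate_prob = NULL) {
  targets <- line_targets()
  if (!line %in% names(targets)) {
    abort(sprintf("unknown line '%s'; presets exist for %s.",
                  line, paste(names(targets), collapse = ", ")))
  }
  tg <- targets[[line]]
  p <- tg$type_probs / sum(tg$type_probs)
  p3 <- p[["type3"]]
  if (p3 >= 1) abort("a preset needs a positive fraction of chloroplast-bearing GCs.")

  e_n <- tg$count_mean / (1 - p3)   # chloroplasts per non-type-3 GC
  count_mu <- count_solve_mu(e_n, tg$count_sd, tg$count_lo, tg$count_hi)

  p_cond1 <- p[["type1"]] / (1 - p3)
  p_cond2 <- p[["type2"]] / (1 - p3)
  if (p_cond1 > 0 && e_n > 1) {
    g1_target <- tg$freq[["giant"]] * e_n / p_cond1
    extra_giant_prob <- min(max((g1_target - 1) / (e_n - 1), 0), 0.6)
  } else {
    extra_giant_prob <- 0
  }
  g1_eff <- 1 + extra_giant_prob * (e_n - 1)
  f_giant <- p_cond1 * g1_eff / e_n

  # eligible small slots: all smalls of type-1 GCs, all but the first
  # (forced-normal) chloroplast of type-2 GCs
  eligible <- p_cond1 * (e_n - g1_eff) + p_cond2 * (e_n - 1)
  mini_prob <- if (eligible > 0) {
    min(max(tg$freq[["mini"]] * e_n / eligible, 0), 1)
  } else {
    0
  }
  f_mini <- eligible * mini_prob / e_n
  f_normal <- 1 - f_giant - f_mini

  giant_lo <- 6.05                      # strictly giant even after 2-dp rounding
  mini_hi <- 1.95                       # strictly mini even after 2-dp rounding
  mini_lo <- max(0.4, tg$len_min)
  normal_mean <- (tg$len_mean - f_giant * tg$giant_len_mean -
                    f_mini * tg$mini_len_mean) / f_normal
  if (normal_mean <= 2.1 || normal_mean >= 5.9) {
    abort(sprintf("calibrated normal-class mean %.2f outside the 2-6 um class.",
                  normal_mean))
  }

  len <- list(
    giant = list(mu = tnorm_solve_mu(tg$giant_len_mean, tg$giant_len_sd,
                                     giant_lo, tg$len_max),
                 sigma = tg$giant_len_sd, lo = giant_lo, hi = tg$len_max),
    normal = list(mu = tnorm_solve_mu(normal_mean, tg$normal_len_sd, 2, 6),
                  sigma = tg$normal_len_sd, lo = 2, hi = 6),
    mini = list(mu = if (mini_prob > 0) {
                  tnorm_solve_mu(tg$mini_len_mean, tg$mini_len_sd, mini_lo, mini_hi)
                } else tg$mini_len_mean,
                sigma = tg$mini_len_sd, lo = mini_lo, hi = mini_hi),
    type3 = list(mu = 1.2, sigma = 0.4, lo = 0.4, hi = mini_hi),
    nongreen = list(mu = 1.8, sigma = 0.6, lo = 0.4, hi = 4)
  )

  structure(
    list(
      line = line,
      type_probs = p,
      kappa = if (is.null(kappa)) tg$kappa else kappa,
      count = list(mu = count_mu, sigma = tg$count_sd,
                   lo = tg$count_lo, hi = tg$count_hi, mean_cond = e_n),
      extra_giant_prob = extra_giant_prob,
      mini_prob = mini_prob,
      len = len,
      type3 = list(count_min = 5, count_lambda = 10,
                   reticulate_prob = if (is.null(reticulate_prob)) {
                     tg$reticulate_prob
                   } else reticulate_prob),
      nongreen_lambda = tg$nongreen_lambda,
      targets = tg
    ),
    class = "line_params"
  )
}

#' @export
print.line_params <- function(x, ...) {
  cat(sprintf(
    "line_params '%s': type_probs = (%.3f, %.3f, %.3f), kappa = %.2f\n",
    x$line, x$type_probs[1], x$type_probs[2], x$type_probs[3], x$kappa
  ))
  cat(sprintf("  chloroplasts/GC (non-type-3): mean %.2f, clamp [%d, %d]\n",
              x$count$mean_cond, x$count$lo, x$count$hi))
  cat(sprintf("  extra-giant prob %.3f, mini prob %.3f\n",
              x$extra_giant_prob, x$mini_prob))
  invisible(x)
}

# One GC's plastids as parallel vectors; uses the current RNG state.
sample_gc <- function(type, params) {
  cn <- params$count
  draw_len <- function(n, comp) rtnorm(n, comp$mu, comp$sigma, comp$lo, comp$hi)
  draw_smalls <- function(s, mini_forbidden_first = FALSE) {
    if (s == 0) return(numeric(0))
    is_mini <- runif(s) < params$mini_prob
    if (mini_forbidden_first) is_mini[1] <- FALSE
    out <- numeric(s)
    out[is_mini] <- draw_len(sum(is_mini), params$len$mini)
    out[!is_mini] <- draw_len(sum(!is_mini), params$len$normal)
    out
  }

  if (type == "type3") {
    m <- params$type3$count_min + rpois(1, params$type3$count_lambda)
    ret <- runif(1) < params$type3$reticulate_prob
    return(list(
      length_um = draw_len(m, params$len$type3),
      chlorophyllous = rep(FALSE, m),
      reticulate = rep(ret, m)
    ))
  }

  n <- rcount(1, cn$mu, cn$sigma, cn$lo, cn$hi)
  if (type == "type1") {
    g <- 1L + rbinom(1, n - 1L, params$extra_giant_prob)
    lens <- c(draw_len(g, params$len$giant), draw_smalls(n - g))
  } else {
    lens <- draw_smalls(n, mini_forbidden_first = TRUE)
  }
  chl <- rep(TRUE, length(lens))
  extras <- rpois(1, params$nongreen_lambda)
  if (extras > 0) {
    lens <- c(lens, draw_len(extras, params$len$nongreen))
    chl <- c(chl, rep(FALSE, extras))
  }
  list(length_um = lens, chlorophyllous = chl,
       reticulate = rep(FALSE, length(lens)))
}

#' Sample one synthetic stoma (a pair of guard cells)
#'
#' Draws the pair's GC types — a single shared draw with probability
#' `kappa`, independent draws otherwise — and then each GC's plastid
#' collection from the type's composition model. Uses (and advances) the
#' current RNG state; seed-scoped generation is provided by
#' [generate_population()].
#'
#' @param params A `line_params` object from [default_params()].
#' @return List with `type_a`, `type_b` and `gc_a`, `gc_b` (each a list of
#'   `length_um`, `chlorophyllous`, `reticulate`).
#' @export
sample_stoma_pair <- function(params) {
  types <- names(params$type_probs)
  if (runif(1) < params$kappa) {
    ty <- sample(types, 1, prob = params$type_probs)
    ta <- ty
    tb <- ty
  } else {
    ta <- sample(types, 1, prob = params$type_probs)
    tb <- sample(types, 1, prob = params$type_probs)
  }
  list(type_a = ta, type_b = tb,
       gc_a = sample_gc(ta, params),
       gc_b = sample_gc(tb, params))
}

#' Generate a synthetic guard-cell population
#'
#' Draws `n_pairs` independent stomata from a line preset (or explicit
#' parameters) and returns the standard tidy plastid table. Reproducible:
#' the same seed yields a byte-identical table. Lengths are reported to
#' 0.01 um, the working precision of the length measurements; the length
#' components are bounded away from the 2 um and 6 um class boundaries so
#' rounding never changes a plastid's size class.
#'
#' @param line Preset name, ignored when `params` is supplied.
#' @param n_pairs Number of stomata (GC pairs) to generate.
#' @param seed Integer seed; recorded as an attribute.
#' @param params Optional `line_params` overriding the preset.
#' @return Tibble with columns `line`, `stoma_id`, `gc_id`, `plastid_id`,
#'   `length_um`, `chlorophyllous`, `reticulate`, plus attributes `params`
#'   and `seed`.
#' @export
generate_population <- function(line = "WT", n_pairs = 100, seed, params = NULL) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1) {
    abort("`seed` must be a single integer.")
  }
  if (n_pairs < 1) abort("`n_pairs` must be >= 1.")
  if (is.null(params)) params <- default_params(line)
  if (!inherits(params, "line_params")) abort("`params` must be a line_params object.")

  pairs <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_pairs), function(i) sample_stoma_pair(params))
  })

  per_gc <- vector("list", 2L * n_pairs)
  for (i in seq_len(n_pairs)) {
    sid <- sprintf("s%04d", i)
    for (side in c("a", "b")) {
      gc <- pairs[[i]][[paste0("gc_", side)]]
      m <- length(gc$length_um)
      gc_id <- paste0(sid, "_", side)
      per_gc[[2L * (i - 1L) + (side == "b") + 1L]] <- list(
        stoma_id = rep(sid, m),
        gc_id = rep(gc_id, m),
        plastid_id = sprintf("%s_p%02d", gc_id, seq_len(m)),
        length_um = round(gc$length_um, 2),
        chlorophyllous = gc$chlorophyllous,
        reticulate = gc$reticulate
      )
    }
  }
  out <- tibble(
    line = params$line,
    stoma_id = unlist(lapply(per_gc, `[[`, "stoma_id")),
    gc_id = unlist(lapply(per_gc, `[[`, "gc_id")),
    plastid_id = unlist(lapply(per_gc, `[[`, "plastid_id")),
    length_um = unlist(lapply(per_gc, `[[`, "length_um")),
    chlorophyllous = unlist(lapply(per_gc, `[[`, "chlorophyllous")),
    reticulate = unlist(lapply(per_gc, `[[`, "reticulate"))
  )
  attr(out, "params") <- params
  attr(out, "seed") <- as.integer(seed)
  out
}
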