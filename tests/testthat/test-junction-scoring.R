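test_that("aggregate_score matches the Bayesian ratio form", {
  expect_equal(aggregate_score(0.7), 0.7)
  expect_equal(aggregate_score(rep(0.5, 3)), 0.5)
  expect_equal(aggregate_score(c(0.9, 0.9)), 0.81 / (0.81 + 0.01),
               tolerance = 1e-12)
  expect_error(aggregate_score(numeric()), "at least one")
  expect_error(aggregate_score(c(0.5, 1)), "strictly inside")

  # ratio form is the oracle for the log-odds implementation
  ratio_form <- function(p) prod(p) / (prod(p) + prod(1 - p))
  withr::with_seed(21, {
    for (i in 1:200) {
      p <- runif(sample(1:10, 1), 0.01, 0.99)
      expect_equal(aggregate_score(p), ratio_form(p), tolerance = 1e-9)
      expect_equal(aggregate_score(rev(p)), aggregate_score(p))
    }
  })
})

test_that("aggregate_score is strictly increasing in each read score", {
  withr::with_seed(22, {
    p <- runif(5, 0.2, 0.8)
    base <- aggregate_score(p)
    for (i in seq_along(p)) {
      bumped <- p; bumped[i] <- bumped[i] + 0.05
      expect_gt(aggregate_score(bumped), base)
    }
  })
})

test_that("null regime switches from empirical to gaussian at the boundary", {
  pool <- withr::with_seed(23, runif(100, 0.1, 0.9))
  n15 <- build_null(pool, 15, reps = 500, seed = 1)
  n16 <- build_null(pool, 16, reps = 500, seed = 1)
  expect_equal(n15$kind, "empirical")
  expect_equal(length(n15$null_p), 500L)
  expect_equal(n16$kind, "gaussian")
  ell <- log((1 - pool) / pool)
  expect_equal(n16$mu, mean(ell))
  expect_equal(n16$sigma, sd(ell))
  expect_error(build_null(0.5, 3), "at least 2")
})

test_that("degenerate pool gives an all-tied null and mid-rank P_cum of 0.5", {
  pool <- rep(0.6, 30)
  null <- build_null(pool, 3, reps = 200, seed = 4)
  expect_true(all(null$null_p == aggregate_score(rep(0.6, 3))))
  expect_equal(cumulative_score(rep(0.6, 3), null), 0.5)
})

test_that("P_cum hits the boundaries and the gaussian center correctly", {
  pool <- withr::with_seed(24, runif(200, 0.3, 0.7))
  null <- build_null(pool, 4, reps = 1000, seed = 5)
  # observed evidence stronger than every null draw
  expect_equal(cumulative_score(rep(0.999, 4), null), 1)
  expect_equal(cumulative_score(rep(0.001, 4), null), 0)
  expect_error(cumulative_score(rep(0.5, 3), null), "N = 4")

  # symmetric pool: mean log-odds 0, so an all-0.5 junction sits at the center
  sym_pool <- c(pool, 1 - pool)
  g <- build_null(sym_pool, 16, seed = 6)
  expect_equal(g$mu, 0, tolerance = 1e-12)
  expect_equal(cumulative_score(rep(0.5, 16), g), 0.5)

  # zero-variance gaussian null falls back to the sign rule
  g0 <- build_null(rep(0.6, 50), 20, seed = 7)
  expect_equal(g0$sigma, 0)
  expect_equal(cumulative_score(rep(0.9, 20), g0), 1)  # stronger evidence
  expect_equal(cumulative_score(rep(0.2, 20), g0), 0)
  expect_equal(cumulative_score(rep(0.6, 20), g0), 0.5)
})

test_that("empirical-null mean for N=2 matches exhaustive enumeration", {
  pool <- withr::with_seed(25, runif(50, 0.05, 0.95))
  null <- build_null(pool, 2, reps = 10000, seed = 8)
  pairs <- expand.grid(i = seq_along(pool), j = seq_along(pool))
  exact <- mean(mapply(function(i, j) aggregate_score(pool[c(i, j)]),
                       pairs$i, pairs$j))
  mc_se <- sd(null$null_p) / sqrt(null$reps)
  expect_lt(abs(mean(null$null_p) - exact), 3 * mc_se)
})

test_that("empirical and gaussian regimes agree near the boundary", {
  pool <- withr::with_seed(26, runif(500, 0.1, 0.9))
  for (s_target in c(-4, 0, 4)) {
    p15 <- rep(plogis(-s_target / 15), 15)
    p16 <- rep(plogis(-s_target / 16), 16)
    pc_emp <- cumulative_score(p15, build_null(pool, 15, reps = 10000, seed = 9))
    pc_gau <- cumulative_score(p16, build_null(pool, 16, seed = 9))
    expect_lt(abs(pc_emp - pc_gau), 0.05)
  }
})

test_that("empirical p-values follow the add-one artifact-rank rule", {
  art <- seq(0.001, 0.999, length.out = 999)
  expect_equal(empirical_p(1, art)$emp_p, 1 / 1000)
  expect_equal(empirical_p(min(art), art)$emp_p, 1)
  # tie at the artifact-set minimum with M = 9
  art9 <- seq(0.1, 0.9, by = 0.1)
  r <- empirical_p(0.1, art9, min_artifact = 5)
  expect_equal(r$emp_p, 10 / 10)
  expect_false(r$fallback)

  # monotone: lowering observed P_cum never lowers emp_p
  obs <- sort(withr::with_seed(29, runif(20)))
  e <- empirical_p(obs, art)$emp_p
  expect_true(all(diff(e) <= 0 | diff(obs) == 0))
  expect_true(all(e > 0 & e <= 1))

  expect_warning(r2 <- empirical_p(0.7, runif(10)), "falling back")
  expect_equal(r2$emp_p, 0.3)
  expect_true(r2$fallback)
})

test_that("collapse_to_junctions groups by intron coordinates", {
  rec <- rbind(make_records(2, intron_start = 500, intron_end = 700),
               make_records(3, intron_start = 900, intron_end = 1100,
                            align_start = c(880, 880, 885)))
  p <- rep(0.8, 5)
  jt <- collapse_to_junctions(rec, p)
  expect_equal(nrow(jt), 2L)
  expect_equal(jt$N, c(2L, 3L))
  expect_equal(jt$n_distinct_offsets, c(2L, 2L))
  expect_equal(jt$P[1], aggregate_score(c(0.8, 0.8)))
})

test_that("the four sample filters apply the documented thresholds", {
  jt <- tibble::tibble(
    frac_genomic = c(0.05, 0.1, 0.05, 0.05, 0.05),
    n_distinct_offsets = c(3L, 3L, 1L, 3L, 3L),
    mean_longest_run = c(5, 5, 5, 12, 5),
    mean_entropy = c(3.5, 3.5, 3.5, 3.5, 2.5)
  )
  out <- sample_filters(jt)
  expect_equal(out$pass_genomic_fraction, c(TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(out$pass_offset_diversity, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(out$pass_homopolymer, c(TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(out$pass_entropy, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(out$eligible_for_median, c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("single-read junctions fail offset diversity and stay ineligible", {
  rec <- make_records(1)
  jt <- sample_filters(collapse_to_junctions(rec, 0.9))
  expect_false(jt$pass_offset_diversity)
  expect_false(jt$eligible_for_median)
})

test_that("score_junctions is reproducible and scores every junction", {
  withr::with_seed(27, {
    rec <- dplyr::bind_rows(lapply(1:12, function(j) {
      make_records(sample(2:20, 1), intron_start = 1000L * j,
                   intron_end = 1000L * j + 300L,
                   genomic = j > 8)
    }))
  })
  p <- withr::with_seed(28, runif(nrow(rec), 0.05, 0.95))
  j1 <- score_junctions(rec, p, sample_id = "s1", null_reps = 2000,
                        min_artifact = 2, seed = 11)
  j2 <- score_junctions(rec, p, sample_id = "s1", null_reps = 2000,
                        min_artifact = 2, seed = 11)
  expect_identical(j1, j2)
  expect_equal(nrow(j1), 12L)
  expect_true(all(!is.na(j1$P_cum)))
  expect_true(all(j1$emp_p > 0 & j1$emp_p <= 1))
  expect_setequal(unique(j1$null_kind[j1$N > 15]), "gaussian")
})
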