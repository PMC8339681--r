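# Synthetic feature tables with a known generative direction: positives look
# like true spliced reads (complex sequence, unique mapping, few mismatches),
# negatives like artifacts.
sim_features <- function(n_pos, n_neg, separable = FALSE) {
  n <- n_pos + n_neg
  pos <- seq_len(n_pos)
  entropy <- c(rnorm(n_pos, 4.0, if (separable) 0.05 else 0.3),
               rnorm(n_neg, 2.2, if (separable) 0.05 else 0.5))
  nh <- c(rep(1, n_pos), if (separable) rep(10, n_neg) else 2 + rpois(n_neg, 5))
  nmm <- c(rpois(n_pos, 0.3), rpois(n_neg, 2))
  overlap <- sample(10:28, n, replace = TRUE)
  feats <- tibble::tibble(
    read_id = sprintf("r%05d", seq_len(n)),
    as_norm = c(rnorm(n_pos, 0.95, 0.03), rnorm(n_neg, 0.85, 0.05)),
    nh = nh, nmm = nmm,
    overlap = overlap,
    max_overlap = overlap + sample(0:20, n, replace = TRUE),
    softclip_s = c(rpois(n_pos, 0.5), rpois(n_neg, 1.5)),
    entropy = pmax(entropy, 0.1)
  )
  list(features = feats, has_genomic = rep(c(FALSE, TRUE), c(n_pos, n_neg)))
}

test_that("training classes come from genomic co-alignment, capped with a seed", {
  sf <- withr::with_seed(1, sim_features(5, 3))
  ts <- build_training_set(sf$features, sf$has_genomic, seed = 1)
  expect_equal(ts$n_pos, 5L)
  expect_equal(ts$n_neg, 3L)
  expect_equal(ts$y, rep(1:0, c(5, 3)))

  # capping draws a uniform random subset, reproducibly
  sf2 <- withr::with_seed(2, sim_features(50, 40))
  ts_a <- build_training_set(sf2$features, sf2$has_genomic, cap = 12, seed = 7)
  ts_b <- build_training_set(sf2$features, sf2$has_genomic, cap = 12, seed = 7)
  expect_equal(ts_a$n_pos, 12L)
  expect_equal(ts_a$n_neg, 12L)
  expect_identical(ts_a$x$read_id, ts_b$x$read_id)
  ts_c <- build_training_set(sf2$features, sf2$has_genomic, cap = 12, seed = 8)
  expect_false(identical(ts_a$x$read_id, ts_c$x$read_id))

  expect_error(build_training_set(sf$features, rep(FALSE, 8)),
               "untrainable sample")
})

test_that("a separable training set yields fully ordered read scores", {
  sf <- withr::with_seed(3, sim_features(300, 300, separable = TRUE))
  ts <- build_training_set(sf$features, sf$has_genomic, seed = 3)
  m <- fit_read_model(ts, seed = 3)
  p <- score_reads(m, sf$features)
  expect_gt(min(p[!sf$has_genomic]), max(p[sf$has_genomic]))
  expect_true(all(p > 0 & p < 1))
})

test_that("random labels produce no separation between classes", {
  sf <- withr::with_seed(4, sim_features(1000, 1000))
  shuffled <- withr::with_seed(5, sample(sf$has_genomic))
  ts <- build_training_set(sf$features, shuffled, seed = 4)
  m <- fit_read_model(ts, seed = 4)
  p <- score_reads(m, sf$features)
  expect_lt(abs(mean(p[shuffled]) - mean(p[!shuffled])), 0.05)
})

test_that("fitting is deterministic under a fixed seed", {
  sf <- withr::with_seed(6, sim_features(400, 400))
  ts <- build_training_set(sf$features, sf$has_genomic, seed = 6)
  m1 <- fit_read_model(ts, seed = 6)
  m2 <- fit_read_model(ts, seed = 6)
  expect_identical(m1$coefficients, m2$coefficients)
})

test_that("fitted coefficient signs recover the generative direction", {
  hits <- withr::with_seed(10, {
    vapply(1:5, function(i) {
      sf <- sim_features(800, 800)
      ts <- build_training_set(sf$features, sf$has_genomic, seed = i)
      m <- fit_read_model(ts, seed = i)
      b <- m$coefficients
      (b[["entropy"]] > 0) && (b[["nh"]] < 0) && (b[["nmm"]] < 0)
    }, logical(1))
  })
  expect_true(all(hits))
})

test_that("scoring is stateless, order-invariant and respects the link", {
  sf <- withr::with_seed(8, sim_features(300, 300))
  ts <- build_training_set(sf$features, sf$has_genomic, seed = 8)
  m <- fit_read_model(ts, seed = 8)
  p_batch <- score_reads(m, sf$features)
  p_single <- vapply(seq_len(10), function(i)
    score_reads(m, sf$features[i, , drop = FALSE]), numeric(1))
  expect_equal(p_batch[1:10], p_single)

  perm <- withr::with_seed(9, sample(nrow(sf$features)))
  expect_equal(score_reads(m, sf$features[perm, ]), p_batch[perm])

  # a record whose standardized features are all zero scores logistic(intercept)
  m_origin <- m
  m_origin$center[["overlap_x_max_overlap"]] <-
    m$center[["overlap"]] * m$center[["max_overlap"]]
  origin <- tibble::as_tibble(as.list(
    m_origin$center[setdiff(names(m_origin$center), "overlap_x_max_overlap")]))
  expect_equal(score_reads(m_origin, origin),
               stats::plogis(m$coefficients[["(Intercept)"]]),
               tolerance = 1e-12, ignore_attr = TRUE)

  # monotonicity: with a positive entropy coefficient, raising entropy raises p
  expect_gt(m$coefficients[["entropy"]], 0)
  lo <- sf$features[1, ]; hi <- lo
  lo$entropy <- 2; hi$entropy <- 4.5
  expect_gt(score_reads(m, hi), score_reads(m, lo))
})

test_that("model serialization round-trips to identical scores", {
  sf <- withr::with_seed(12, sim_features(200, 200))
  ts <- build_training_set(sf$features, sf$has_genomic, seed = 12)
  m <- fit_read_model(ts, seed = 12)
  path <- tempfile(fileext = ".txt")
  write_read_model(m, path)
  m2 <- read_read_model(path)
  expect_equal(score_reads(m2, sf$features), score_reads(m, sf$features))
  expect_equal(m2$penalty$lambda, m$penalty$lambda)
})

test_that("paired mode uses the paired predictor set", {
  sf <- withr::with_seed(13, sim_features(200, 200))
  f <- sf$features
  f$mate_as_norm <- f$as_norm; f$mate_nh <- f$nh; f$mate_nmm <- f$nmm
  f$mate_overlap <- f$overlap; f$mate_max_overlap <- f$max_overlap
  f$mate_softclip_s <- f$softclip_s; f$mate_entropy <- f$entropy
  f$location_compatible <- rep(c(1, 0), c(200, 200))
  f$strand_compatible <- rep(c(1, 0), c(200, 200))
  ts <- build_training_set(f, sf$has_genomic, seed = 13)
  m <- fit_read_model(ts, mode = "paired", seed = 13)
  expect_true(all(c("mate_entropy", "location_compatible", "strand_compatible",
                    "mate_overlap_x_max_overlap") %in% names(m$coefficients)))
  # a paired model refuses a feature table without the mate fields
  expect_error(score_reads(m, sf$features), "missing field")
})
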