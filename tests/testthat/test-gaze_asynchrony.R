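test_that("window segmentation follows the 250 ms / 50 ms sliding rule", {
  tr <- uniform_traces(2, 600)
  wins <- segment_windows(tr)
  expect_identical(nrow(wins), 196L)           # floor((600 - 15)/3) + 1
  expect_identical(wins$start_sample[1:3], c(0L, 3L, 6L))
  expect_equal(1 - 3 / 15, 0.8)                # 80% overlap by construction
  expect_identical(nrow(segment_windows(uniform_traces(2, 10))), 0L)
  expect_identical(nrow(segment_windows(uniform_traces(2, 15))), 1L)
})

test_that("pairwise distances are time-matched Euclidean pixels", {
  n <- 30
  a <- mk_traces(function(p) cbind(rep(0, n), rep(0, n)), 1, n)[[1]]
  b <- mk_traces(function(p) cbind(rep(3, n), rep(4, n)), 1, n)[[1]]
  d <- pairwise_gaze_distances(list(a, b), 0)
  expect_length(d, 15L)
  expect_true(all(d == 5))
  expect_true(all(pairwise_gaze_distances(list(a, a), 0) == 0))
  tr4 <- uniform_traces(4, n)
  expect_length(pairwise_gaze_distances(tr4, 0), choose(4, 2) * 15)
  expect_length(pairwise_gaze_distances(list(a), 0), 0L)  # unclassifiable
})

test_that("the permutation null is deterministic and degenerates on constants", {
  tr <- uniform_traces(4, 120, seed = 3)
  n1 <- estimate_null_distribution(tr, n_draws = 50, seed = 9)
  n2 <- estimate_null_distribution(tr, n_draws = 50, seed = 9)
  expect_identical(n1$q_lo, n2$q_lo)
  expect_identical(n1$q_hi, n2$q_hi)
  const <- mk_traces(function(p) cbind(rep(100, 120), rep(200, 120)), 3, 120)
  nd <- estimate_null_distribution(const, n_draws = 20, seed = 1)
  expect_true(nd$degenerate)
  expect_identical(c(nd$q_lo, nd$q_hi), c(0, 0))
})

test_that("null quantiles match a Monte-Carlo oracle for uniform gaze", {
  # for i.i.d. uniform points, shuffling windows changes nothing: the null
  # is the distance distribution of two uniform points on the screen
  tr <- uniform_traces(6, 1200, seed = 7)
  nd <- estimate_null_distribution(tr, n_draws = 200, seed = 11)
  set.seed(99)
  d <- sqrt((runif(2e5, 0, 1024) - runif(2e5, 0, 1024))^2 +
              (runif(2e5, 0, 768) - runif(2e5, 0, 768))^2)
  q <- quantile(d, c(0.05, 0.95))
  expect_lt(abs(nd$q_lo - q[[1]]), 15)         # a few px of MC error
  expect_lt(abs(nd$q_hi - q[[2]]), 15)
})

test_that("window classification applies the 30% inside rule with >= ties", {
  null <- structure(list(q_lo = 1, q_hi = 2, n_draws = 10, seed = 1,
                         n_pool = 100, ci_level = 0.9, degenerate = FALSE),
                    class = "null_distribution")
  expect_identical(classify_window(rep(1.5, 10), null), "divergent")
  expect_identical(classify_window(rep(0.5, 10), null), "non_divergent")
  expect_identical(classify_window(c(rep(1.5, 3), rep(10, 7)), null),
                   "divergent")               # share exactly 0.30
  expect_identical(classify_window(c(rep(1.5, 2), rep(10, 8)), null),
                   "non_divergent")
  expect_identical(classify_window(numeric(), null), "unclassifiable")
  null$degenerate <- TRUE
  expect_identical(classify_window(rep(1.5, 10), null), "non_divergent")
  # outside rule inverts the region
  null$degenerate <- FALSE
  expect_identical(classify_window(rep(10, 10), null, rule = "outside"),
                   "divergent")
})

test_that("asynchrony hits its limits: uniform ~ 1, synchronized ~ 0", {
  sc_u <- attentional_asynchrony(uniform_traces(8, 1200, seed = 2),
                                 n_draws = 200, seed = 5)$score
  expect_gte(sc_u, 0.95)
  sc_s <- attentional_asynchrony(synchronized_traces(8, 1200, seed = 2),
                                 n_draws = 200, seed = 5)$score
  expect_lte(sc_s, 0.05)
  expect_true(sc_u >= 0 && sc_u <= 1 && sc_s >= 0 && sc_s <= 1)
})

test_that("relabeling participants or viewings never changes the score", {
  tr <- uniform_traces(5, 300, seed = 8)
  s0 <- attentional_asynchrony(tr, n_draws = 50, seed = 3)$score
  relab <- lapply(tr, function(x) {
    x$participant <- paste0("z_", x$participant)
    x$viewing <- 3L - x$viewing
    x
  })
  expect_identical(attentional_asynchrony(relab, n_draws = 50, seed = 3)$score,
                   s0)
})

test_that("invalid samples carry no information", {
  tr <- uniform_traces(5, 300, seed = 12)
  flip <- withr::with_seed(13, sample(300, 30))
  a <- lapply(tr, function(x) { x$valid[flip] <- FALSE; x })
  b <- lapply(a, function(x) {                # garbage behind the flag
    x$xy[flip, ] <- 1e6
    x
  })
  sa <- attentional_asynchrony(a, n_draws = 50, seed = 3)$score
  sb <- attentional_asynchrony(b, n_draws = 50, seed = 3)$score
  expect_identical(sa, sb)
})

test_that("degenerate inputs raise the documented errors", {
  expect_error(attentional_asynchrony(uniform_traces(1, 100)), ">= 2 traces")
  expect_error(attentional_asynchrony(uniform_traces(3, 10)),
               "too short")
  short <- c(uniform_traces(2, 100), uniform_traces(1, 50))
  expect_error(attentional_asynchrony(short), "inconsistent grids")
})
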