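test_that("OLS satisfies its identities and recovers exact fits", {
  x <- 1:5
  fit <- fit_linear_model(x, 2 * x)
  expect_equal(fit$r2, 1)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-12)
  set.seed(40)
  for (r in 1:20) {
    n <- sample(8:30, 1); k <- sample(1:2, 1)
    X <- matrix(rnorm(n * k), n)
    y <- rnorm(n)
    f <- fit_linear_model(X, y)
    expect_equal(f$r2_adj, 1 - (1 - f$r2) * (n - 1) / (n - k - 1),
                 tolerance = 1e-10)
    expect_equal(f$F, (f$r2 / k) / ((1 - f$r2) / (n - k - 1)),
                 tolerance = 1e-10)
    expect_identical(f$df, c(k, n - k - 1L))
  }
})

test_that("R2 matches a normal-equations oracle", {
  x <- 1:6
  y <- c(2, 1, 4, 3, 6, 5)
  f <- fit_linear_model(x, y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  r2 <- 1 - sum((y - X %*% beta)^2) / sum((y - mean(y))^2)
  expect_equal(f$r2, r2, tolerance = 1e-10)
  expect_equal(unname(f$coefficients), unname(drop(beta)), tolerance = 1e-10)
})

test_that("a dataset engineered to R2 = 0.49 yields F(1,12) = 11.53", {
  # orthogonalize noise against x, then scale it to pin R2 exactly
  set.seed(41)
  n <- 14
  x <- scale(rnorm(n))[, 1]
  e <- residuals(lm(rnorm(n) ~ x))
  e <- e / sqrt(sum(e^2)) * sqrt(sum(x^2) * (1 - 0.49) / 0.49)
  f <- fit_linear_model(x, x + e)
  expect_equal(f$r2, 0.49, tolerance = 1e-10)
  expect_equal(f$F, 11.53, tolerance = 0.005)
  expect_equal(round(adjusted_r2(0.7370, 14, 2), 2), 0.69)
})

test_that("degenerate regression inputs are refused", {
  expect_error(fit_linear_model(rep(1, 5), rnorm(5)), "constant predictor")
  expect_error(fit_linear_model(rnorm(5), rep(2, 5)), "zero-variance")
  expect_error(fit_linear_model(rnorm(2), rnorm(2)), "too small")
})

test_that("the bootstrap SE of R2 is zero for perfect fits, reproducible,
           and close to an independent oracle", {
  x <- 1:8
  expect_equal(bootstrap_r2_se(x, 3 * x - 1, B = 200, seed = 1), 0)
  set.seed(42)
  y <- x + rnorm(8)
  s1 <- bootstrap_r2_se(x, y, B = 500, seed = 7)
  expect_identical(bootstrap_r2_se(x, y, B = 500, seed = 7), s1)
  # independent oracle: plain lm() refits on its own resampling stream
  oracle <- withr::with_seed(1234, {
    r2s <- replicate(4000, {
      repeat {
        i <- sample(8, replace = TRUE)
        if (sd(x[i]) > 0 && sd(y[i]) > 0) break
      }
      suppressWarnings(summary(lm(y[i] ~ x[i]))$r.squared)
    })
    sd(r2s)
  })
  s2 <- bootstrap_r2_se(x, y, B = 4000, seed = 8)
  expect_lt(abs(s2 - oracle) / oracle, 0.10)
  expect_error(bootstrap_r2_se(x, y, B = 1), "B must be")
})

test_that("BH adjustment matches hand computation and is order invariant", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.001, 0.2, 0.04, 0.9)
  perm <- c(3, 1, 4, 2)
  expect_equal(fdr_adjust(p[perm]), fdr_adjust(p)[perm])
  # hand BH: sorted p * n / rank, cummin from the largest
  expect_equal(fdr_adjust(c(0.01, 0.04, 0.03, 0.002)),
               c(0.02, 0.04, 0.04, 0.008))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the correlation screen matches the textbook formula", {
  st <- data.frame(a = 1:6, b = -(1:6), c = c(2, 1, 4, 3, 6, 5),
                   k = 1:6)
  sc <- correlation_screen(st, c("a", "b", "c"), "k")
  expect_equal(sc$r[1], 1)
  expect_equal(sc$r[2], -1)
  x <- st$c; y <- st$k
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(sc$r[3], r_hand, tolerance = 1e-12)
  st$const <- 5
  expect_warning(sc2 <- correlation_screen(st, "const", "k"), "undefined")
  expect_true(is.na(sc2$r))
})

test_that("the weekend sweep has the 7 x 9 layout and per-row FDR", {
  study <- toy_study()
  sw <- weekend_sweep(study, B = 0)
  expect_identical(nrow(sw), 63L)
  expect_identical(length(unique(sw$model)), 7L)
  expect_identical(length(unique(sw$outcome)), 9L)
  for (m in unique(sw$model)) {
    rows <- sw[sw$model == m, ]
    expect_equal(rows$p_fdr, fdr_adjust(rows$p))
  }
  # a metric equal to the premiere KPI predicts it perfectly
  study$asy_v1 <- study$premiere
  sw2 <- weekend_sweep(study, B = 0)
  expect_equal(sw2$r2[sw2$model == "Att-Asy-1" & sw2$outcome == "premiere"], 1)
  expect_error(weekend_sweep(study[, -2]), "lacks KPI")
  expect_error(weekend_sweep(study, models = list(M = "nope")), "nope")
})

test_that("a metric unrelated to the KPI survives FDR as null", {
  study <- toy_study()
  study$asy_v1 <- withr::with_seed(77, rnorm(nrow(study)))
  sw <- weekend_sweep(study, models = list("Att-Asy-1" = "asy_v1"), B = 0)
  expect_true(all(sw$p_fdr > 0.05))
})

test_that("bivariate R2 dominates both univariate R2 on the same rows", {
  study <- toy_study()
  for (oc in c("premiere", "wknd3", "wknd8")) {
    r2_1 <- fit_linear_model(study$asy_v1, study[[oc]])$r2
    r2_2 <- fit_linear_model(study$cogn_52_70, study[[oc]])$r2
    r2_b <- fit_linear_model(as.matrix(study[c("asy_v1", "cogn_52_70")]),
                             study[[oc]])$r2
    expect_gte(r2_b, max(r2_1, r2_2) - 1e-12)
  }
})

test_that("outlier-flagged rows are dropped before fitting", {
  study <- toy_study()
  study$outlier <- c(TRUE, rep(FALSE, nrow(study) - 1L))
  sw <- weekend_sweep(study, models = list("Att-Asy-1" = "asy_v1"), B = 0)
  expect_true(all(sw$n == nrow(study) - 1L))
})
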