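rand_pairs <- function(S, D, T, mix = 0) {
  lapply(seq_len(S), function(s) {
    X1 <- matrix(rnorm(D * T), D)
    list(X1 = X1, X2 = mix * X1 + (1 - mix) * matrix(rnorm(D * T), D))
  })
}

test_that("viewing covariances follow their definition", {
  set.seed(10)
  X <- matrix(rexp(3 * 50), 3)
  cv <- viewing_covariances(list(list(X1 = X, X2 = X)))
  expect_equal(cv$R11, cv$R22)
  expect_equal(cv$R11, cv$R12)
  # bilinearity: scaling X by c scales every R by c^2
  cv4 <- viewing_covariances(list(list(X1 = 2 * X, X2 = 2 * X)))
  expect_equal(cv4$R11, 4 * cv$R11)
  expect_equal(cv4$R12, 4 * cv$R12)
})

test_that("covariances match a hand loop on small integer matrices", {
  pairs <- list(list(X1 = matrix(c(1, 2, 3, 4, 5, 6), 2), X2 = matrix(c(2, 0, 1, 1, 0, 3), 2)),
                list(X1 = matrix(c(0, 1, 2, 2, 4, 0), 2), X2 = matrix(c(1, 1, 1, 2, 3, 5), 2)))
  cv <- viewing_covariances(pairs)
  S <- 2; T <- 3
  R11 <- R22 <- R12 <- matrix(0, 2, 2)
  for (p in pairs) {
    x1 <- p$X1 - rowMeans(p$X1); x2 <- p$X2 - rowMeans(p$X2)
    for (i in 1:2) for (j in 1:2) for (t in 1:T) {
      R11[i, j] <- R11[i, j] + x1[i, t] * x1[j, t]
      R22[i, j] <- R22[i, j] + x2[i, t] * x2[j, t]
      R12[i, j] <- R12[i, j] + x1[i, t] * x2[j, t]
    }
  }
  expect_equal(cv$R11, R11 / (S * T))
  expect_equal(cv$R22, R22 / (S * T))
  expect_equal(cv$R12, (R12 + t(R12)) / (2 * S * T))
})

test_that("subject handling: order invariance, exclusions, dimension errors", {
  set.seed(11)
  pairs <- rand_pairs(3, 2, 20)
  cv1 <- viewing_covariances(pairs)
  cv2 <- viewing_covariances(rev(pairs))
  expect_equal(cv1$R11, cv2$R11)
  expect_equal(cv1$R12, cv2$R12)
  expect_warning(cv3 <- viewing_covariances(c(pairs, list(list(X1 = pairs[[1]]$X1, X2 = NULL)))),
                 "excluding 1 subject")
  expect_equal(cv3$R12, cv1$R12)
  expect_error(suppressWarnings(viewing_covariances(list(list(X1 = NULL, X2 = NULL)))),
               "no subject")
  bad <- pairs; bad[[2]]$X2 <- matrix(0, 2, 21)
  expect_error(viewing_covariances(bad), "subject 2")
})

test_that("identical viewings give lambda exactly one half", {
  set.seed(12)
  X <- matrix(rexp(4 * 60), 4)
  res <- cognitive_congruency(list(list(X1 = X, X2 = X)), shrinkage = 0)
  expect_equal(res$lam, 0.5, tolerance = 1e-12)
})

test_that("the eigenvalue matches a dense grid search at D = 2", {
  set.seed(13)
  cv <- viewing_covariances(rand_pairs(2, 2, 200, mix = 0.6))
  lam <- solve_congruency(cv, shrinkage = 0)$lam
  theta <- seq(0, pi, length.out = 1e5)
  quo <- vapply(theta, function(h) {
    w <- c(cos(h), sin(h))
    drop(w %*% cv$R12 %*% w) / drop(w %*% (cv$R11 + cv$R22) %*% w)
  }, 0)
  expect_equal(lam, max(quo), tolerance = 1e-6)
})

test_that("independent viewings give near-zero lambda", {
  set.seed(14)
  res <- cognitive_congruency(rand_pairs(1, 4, 4000, mix = 0))
  expect_lt(abs(res$lam), 0.05)
})

test_that("|lambda| <= 1/2 on random data-generated covariance sets", {
  set.seed(15)
  for (r in 1:100) {
    D <- sample(2:6, 1)
    cv <- viewing_covariances(rand_pairs(1, D, D + sample(2:20, 1),
                                         mix = runif(1)))
    expect_lte(abs(solve_congruency(cv, shrinkage = 0)$lam), 0.5 + 1e-9)
  }
})

test_that("lambda is invariant to a common invertible channel transform", {
  set.seed(16)
  pairs <- rand_pairs(3, 4, 100, mix = 0.5)
  A <- matrix(rnorm(16), 4)
  mixed <- lapply(pairs, function(p) list(X1 = A %*% p$X1, X2 = A %*% p$X2))
  l0 <- cognitive_congruency(pairs, shrinkage = 0)$lam
  l1 <- cognitive_congruency(mixed, shrinkage = 0)$lam
  expect_equal(l0, l1, tolerance = 1e-8)
})

test_that("the forward model is scale-invariant and identity-trivial", {
  cv <- structure(list(R11 = diag(3), R22 = diag(3),
                       R12 = diag(3) * 0.2, n_subjects = 1, T = 10, D = 3,
                       band = NULL, trailer_id = NA),
                  class = "covariance_set")
  w <- c(1, 2, 2)
  a <- forward_model(list(w = w), cv)
  expect_equal(a / sqrt(sum(a^2)), w / sqrt(sum(w^2)))  # a prop. to w
  expect_equal(forward_model(list(w = 2 * w), cv), a)
  expect_error(forward_model(list(w = c(0, 0, 0)), cv), "no variance")
})

test_that("planted topography is recovered at high SNR", {
  cfg <- sim_config(n_subjects = 6, n_trailers = 1, trailer_dur_s = 60,
                    n_channels = 4, snr_congruency = 6, seed = 21)
  st <- simulate_eeg_study(cfg)
  res <- cognitive_congruency(st[[1]]$subjects)
  expect_gte(abs(cor(res$a, st[[1]]$topography)), 0.9)
  expect_gte(res$lam, 0.4)
})

test_that("singular denominators are reported with advice", {
  cv <- structure(list(R11 = matrix(0, 2, 2), R22 = matrix(0, 2, 2),
                       R12 = matrix(0, 2, 2), n_subjects = 1, T = 5, D = 2,
                       band = NULL, trailer_id = NA),
                  class = "covariance_set")
  expect_error(solve_congruency(cv, shrinkage = 0), "larger `shrinkage`")
})
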