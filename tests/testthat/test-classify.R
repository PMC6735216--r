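test_that("CSP filters extremize the class variance ratio (toy cases)", {
  ## classes differing only in the variance of channel 2
  a <- gauss_trials(12, diag(c(1, 3, 1)), seed = 1)
  b <- gauss_trials(12, diag(c(1, 1, 1)), seed = 2)
  f <- csp_fit(a, b)
  w <- f$filters[1, ]
  expect_equal(which.max(abs(w)), 2L)
  expect_gt(w[2]^2 / sum(w^2), 0.9)
  expect_true(all(diff(f$eigenvalues) <= 1e-12))

  ## identical class covariances -> all eigenvalues 1/2
  same <- gauss_trials(40, diag(2), n_samp = 4000, seed = 3)
  f2 <- csp_fit(same[1:20, , , drop = FALSE], same[21:40, , , drop = FALSE])
  expect_equal(f2$eigenvalues, c(0.5, 0.5), tolerance = 0.05)

  expect_error(csp_fit(a[1, , , drop = FALSE], b), "2 trials")
})

test_that("the top CSP filter matches exhaustive unit-filter search", {
  for (seed in 1:5) {
    ## random 2-channel classes with correlated covariances
    withr::with_seed(seed, {
      La <- matrix(rnorm(4), 2, 2) + 2 * diag(2)
      Lb <- matrix(rnorm(4), 2, 2) + 2 * diag(2)
    })
    a <- gauss_trials(10, La, seed = 100 + seed)
    b <- gauss_trials(10, Lb, seed = 200 + seed)
    Ca <- oracle_cov(a)
    Cb <- oracle_cov(b)
    ratio <- function(theta) {
      w <- c(cos(theta), sin(theta))
      (w %*% Ca %*% w) / (w %*% Cb %*% w)
    }
    ## grid at 0.1 degree, then local refinement around the best angle
    grid <- seq(0, pi, by = 0.1 * pi / 180)
    vals <- vapply(grid, ratio, numeric(1))
    k <- which.max(vals)
    best <- stats::optimize(ratio, lower = grid[max(1, k - 2)],
                            upper = grid[min(length(grid), k + 2)],
                            maximum = TRUE, tol = 1e-12)$objective

    w_top <- csp_fit(a, b)$filters[1, ]
    achieved <- (w_top %*% Ca %*% w_top) / (w_top %*% Cb %*% w_top)
    expect_equal(as.numeric(achieved), as.numeric(best), tolerance = 1e-6)
  }
})

test_that("log-variance features scale and count as expected", {
  a <- gauss_trials(8, diag(c(2, 1, 1, 1)), seed = 5)
  b <- gauss_trials(8, diag(4), seed = 6)
  f <- csp_fit(a, b)
  feats <- csp_features(f, a)
  expect_equal(dim(feats), c(8L, 4L))
  ## doubling the amplitude adds log(4) to every log-variance feature
  feats2 <- csp_features(f, a * 2)
  expect_equal(feats2 - feats, matrix(log(4), 8, 4), tolerance = 1e-9)
  ## zero-variance projection is floored, not -Inf
  z <- array(0, c(2, 4, 100))
  expect_true(all(is.finite(csp_features(f, z))))
})

test_that("cross-validation separates variance-coded classes and is seeded", {
  ## attempt trials carry 5x amplitude on channel 1: linearly separable
  ep <- toy_epochs(n_per_class = 10, n_ch = 4,
                   scales = list(attempt = c(5, 1, 1, 1),
                                 blank = rep(1, 4)))
  cv <- crossval_accuracy(ep, paste0("ch", 1:4), seed = 1,
                          bands = list(alpha = c(8, 13), beta = c(13, 30)),
                          window = c(0, 7))
  expect_equal(cv$mean_accuracy, 1)
  expect_length(cv$fold_accuracies, 5L)
  cv2 <- crossval_accuracy(ep, paste0("ch", 1:4), seed = 1,
                           bands = list(alpha = c(8, 13), beta = c(13, 30)),
                           window = c(0, 7))
  expect_identical(cv$fold_accuracies, cv2$fold_accuracies)

  ## feature dimension contract: 2 bands x n channels
  expect_equal(2L * length(cv$channels), 8L)

  expect_error(crossval_accuracy(ep, c("ch1", "nope"), seed = 1), "nope")
})

test_that("accuracy sits at chance when classes are exchangeable", {
  accs <- vapply(1:4, function(s) {
    ep <- toy_epochs(n_per_class = 10, n_ch = 4, seed = 10 + s)
    crossval_accuracy(ep, paste0("ch", 1:4), seed = s,
                      window = c(0, 7))$mean_accuracy
  }, numeric(1))
  ## pooled over 4 x 40 held-out trials: 95% binomial band around 0.5
  expect_gt(mean(accs), 0.5 - 1.96 * sqrt(0.25 / 160) - 0.05)
  expect_lt(mean(accs), 0.5 + 1.96 * sqrt(0.25 / 160) + 0.05)
})

test_that("a class absent from a training fold raises an error", {
  ep <- toy_epochs(n_per_class = 10, n_ch = 2)
  keep <- c(1L, 11:20)    # one attempt trial only
  lone <- epoch_set(ep$data[keep, , , drop = FALSE], ep$labels[keep],
                    ep$sampling_rate, ep$channel_labels)
  expect_error(
    crossval_accuracy(lone, c("ch1", "ch2"), seed = 1, window = c(0, 7)),
    "missing|2 trials"
  )
})
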