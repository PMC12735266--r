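test_that("unlabeled losses square counts, drop clear negatives, normalize", {
  cgt <- matrix(0, 3, 3); cgt[1, 1] <- 1   # one provided positive
  cpre <- matrix(0, 3, 3)
  cpre[2, 2] <- 0.05   # raw 0.0025 -> clear negative
  cpre[3, 1] <- 0.5    # raw 0.25   -> survivor
  cpre[3, 3] <- 1.0    # raw 1.0    -> survivor
  ul <- unlabeled_losses(cpre, cgt)
  expect_equal(sort(ul$raw), c(0.25, 1.0))
  expect_equal(ul$n_clear, 6)  # 8 unlabeled minus 2 survivors
  expect_equal(ul$bounds, c(0.25, 1.0))
  expect_true(all(ul$norm > 0 & ul$norm < 1))
  # the masked coordinate never appears
  expect_false(any(ul$coords$row == 0 & ul$coords$col == 0))
  expect_false(any(ul$clear_coords$row == 0 & ul$clear_coords$col == 0))
  # all-zero prediction: everything is a clear negative
  ul0 <- unlabeled_losses(matrix(0, 3, 3), cgt)
  expect_equal(length(ul0$raw), 0)
  expect_equal(ul0$n_clear, 8)
})

test_that("EM recovers a well-separated two-component mixture", {
  true_mix <- beta_mixture(c(0.5, 0.5), c(2, 18), c(18, 2))
  for (seed in 1:10) {
    x <- sample_beta_mixture(true_mix, 2000, seed = seed)
    fit <- fit_bmm_em(x, seed = seed)
    means <- fit$alpha / (fit$alpha + fit$beta)
    expect_lt(abs(means[1] - 0.1), 0.05)
    expect_lt(abs(means[2] - 0.9), 0.05)
    expect_lt(abs(fit$weights[1] - 0.5), 0.1)
  }
})

test_that("EM log-likelihood is non-decreasing", {
  true_mix <- beta_mixture(c(0.6, 0.4), c(3, 12), c(15, 3))
  x <- sample_beta_mixture(true_mix, 1500, seed = 3)
  fit <- fit_bmm_em(x, seed = 3)
  expect_true(all(diff(fit$loglik) > -1e-8))
})

test_that("a single tight low cluster yields no spurious noisy mode", {
  # unimodal low-loss data: both components settle on the cluster (the
  # weight split between two near-identical components is arbitrary),
  # so what must hold is that no appreciable mass lands at high loss
  x <- sample_beta_mixture(beta_mixture(c(1, 0), c(2, 2.0001), c(18, 18)),
                           1000, seed = 9)
  fit <- fit_bmm_em(x, seed = 9)
  means <- fit$alpha / (fit$alpha + fit$beta)
  expect_true(all(means < 0.2))
  mass_high <- sum(fit$weights * pbeta(0.5, fit$alpha, fit$beta,
                                       lower.tail = FALSE))
  expect_lt(mass_high, 0.01)
})

test_that("posterior behaves at symmetry points and extremes", {
  sym <- beta_mixture(c(0.5, 0.5), c(2, 8), c(8, 2))
  expect_equal(posterior_noisy(sym, 0.5), 0.5, tolerance = 1e-12)
  one <- beta_mixture(c(1, 0), c(2, 8), c(8, 2))
  expect_lt(max(posterior_noisy(one, c(0.1, 0.5, 0.9))), 1e-10)
  # extreme values evaluated in log space without over/underflow
  sharp <- beta_mixture(c(0.5, 0.5), c(1, 200), c(200, 1))
  expect_true(is.finite(posterior_noisy(sharp, 1e-3)))
  expect_true(is.finite(posterior_noisy(sharp, 1 - 1e-3)))
  # monotone in l for stochastically ordered components
  mix <- beta_mixture(c(0.5, 0.5), c(2, 18), c(18, 2))
  ls <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(posterior_noisy(mix, ls)) >= 0))
})

test_that("posterior after a recovery fit is calibrated at the extremes", {
  true_mix <- beta_mixture(c(0.5, 0.5), c(2, 18), c(18, 2))
  x <- sample_beta_mixture(true_mix, 2000, seed = 4)
  fit <- fit_bmm_em(x, seed = 4)
  expect_gt(posterior_noisy(fit, 0.9), 0.95)
  # samples from the noisy component average a higher posterior than
  # samples from the clean one
  clean <- sample_beta_mixture(beta_mixture(c(1, 0), c(2, 2.1), c(18, 18)),
                               400, seed = 5)
  noisy <- sample_beta_mixture(beta_mixture(c(0, 1), c(18, 18), c(18, 2)),
                               400, seed = 6)
  expect_gt(mean(posterior_noisy(fit, noisy)),
            mean(posterior_noisy(fit, clean)))
})

test_that("mixture sampling hits the stated moments and bimodality", {
  mix <- beta_mixture(c(0.5, 0.5), c(2, 18), c(18, 2))
  x <- sample_beta_mixture(mix, 5000, seed = 2)
  expect_lt(abs(mean(x) - 0.5), 0.03)
  h <- hist(x, breaks = seq(0, 1, by = 0.1), plot = FALSE)$counts
  valley <- h[5:6]; modes <- c(max(h[1:3]), max(h[8:10]))
  expect_true(all(valley < modes))
  expect_error(sample_beta_mixture(mix, 0), "at least 1")
})

test_that("degenerate inputs are signaled", {
  expect_error(fit_bmm_em(runif(5)), class = "pulocalize_empty_losses")
  expect_error(fit_bmm_em(c(rep(0.2, 20), 1.5)), "inside")
})

test_that("mixtures round-trip through JSON", {
  mix <- beta_mixture(c(0.3, 0.7), c(2, 9), c(11, 3), bounds = c(0.01, 4))
  path <- tempfile(fileext = ".json")
  write_beta_mixture(mix, path)
  back <- read_beta_mixture(path)
  expect_equal(back$weights, mix$weights, tolerance = 1e-12)
  expect_equal(back$alpha, mix$alpha, tolerance = 1e-12)
  expect_equal(back$bounds, mix$bounds, tolerance = 1e-12)
})
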