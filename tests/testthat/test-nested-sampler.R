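test_that("log_plus is exact and overflow-safe", {
  expect_equal(log_plus(0, 0), log(2))
  expect_equal(log_plus(5, -Inf), 5)
  expect_equal(log_plus(-Inf, -3), -3)
  expect_equal(log_plus(log(1), log(3)), log(4))
  expect_equal(log_plus(1000, 1000), 1000 + log(2))
  expect_equal(log_plus(-1e4, -1e4 + 1), (-1e4 + 1) + log1p(exp(-1)))
})

test_that("initial population respects the prior box and the seed", {
  pr <- uniform_prior(c(0.1, 1), c(0.4, 7))
  set.seed(10)
  pts <- initialize_points(200, pr, function(th) sum(th))
  th <- t(vapply(pts, `[[`, numeric(2), "theta"))
  expect_true(all(th[, 1] >= 0.1 & th[, 1] <= 0.4))
  expect_true(all(th[, 2] >= 1 & th[, 2] <= 7))
  expect_true(all(vapply(pts, function(p) all(p$step_sizes > 0), NA)))
  set.seed(10)
  pts2 <- initialize_points(200, pr, function(th) sum(th))
  expect_identical(pts, pts2)
  expect_error(initialize_points(5, pr, function(th) NaN), "finite")
})

test_that("constant likelihood integrates to itself for any population size", {
  pr <- uniform_prior(c(0, 0), c(1, 1))
  for (n in c(5, 25)) {
    fit <- nested_sampling(function(th) log(0.37), pr, n = n,
                           max_posterior = 40 * n, seed = 1)
    # the trapezoidal width sum telescopes to (1 + e^(-1/n))/2, so the
    # flat-likelihood evidence carries an O(1/(2n)) discretization deficit
    expect_equal(fit$logZ, log(0.37) + log((1 + exp(-1 / n)) / 2),
                 tolerance = 1e-4)
    expect_lt(abs(fit$logZ - log(0.37)), 1 / n)
    # the information inherits the same O(1/(2n)) offset (up to the small
    # live-set remainder at termination) and vanishes with n
    expect_equal(fit$H, -log((1 + exp(-1 / n)) / 2), tolerance = 0.02)
    expect_lt(fit$H, 1 / n)
    expect_lt(fit$logZ_error, 1 / n)
  }
})

test_that("stopping rule: pure-width decay, short history, and the identity", {
  n <- 25
  lw <- function(i) log((exp(-(i - 1) / n) - exp(-(i + 1) / n)) / 2)
  # the log width falls by exactly 50/n over 50 iterations
  expect_equal(lw(10) - lw(60), 50 / n, tolerance = 1e-12)
  expect_equal(lw(123) - lw(173), 2)
  # pure-width regime with high logL* stops; short history continues
  hist <- lw(1:200) + 5
  expect_true(stopping_check(hist, logLstar = 100, i = 200, n = n)$stop)
  expect_false(stopping_check(hist[1:30], logLstar = 100, i = 30, n = n)$stop)
  # low margin blocks termination
  expect_false(stopping_check(hist, logLstar = hist[200] + 1, i = 200,
                              n = n)$stop)
  # cap fires regardless
  expect_true(stopping_check(hist, 0, i = 200, n = n,
                             max_posterior = 150)$stop)
})

test_that("posterior moments from hand-built weighted samples", {
  mk <- function(theta, logWt) {
    samples <- data.frame(iteration = seq_along(theta), a = theta,
                          logL = 0, logWt = logWt)
    structure(list(logZ = log(sum(exp(logWt))), samples = samples, n = 2,
                   m = length(theta),
                   prior = uniform_prior(0, 10, "a")), class = "ns")
  }
  one <- posterior_moments(mk(3, 0))
  expect_equal(one$mean, 3)
  expect_equal(one$sd, 0)
  two <- posterior_moments(mk(c(0, 2), c(log(0.5), log(0.5))))
  expect_equal(two$mean, 1)
  expect_equal(two$sd, 1)
  expect_equal(two$cv, 1)
})

test_that("evidence accumulation is consistent and the logL sequence monotone", {
  bm <- gaussian_benchmark(5)
  fit <- ns_gaussian(bm, seed = 7)
  s <- fit$samples
  # discarded-point likelihoods never decrease (live tail sorted on append)
  expect_true(all(diff(s$logL) >= -1e-12))
  # logZ equals the log-sum-exp of all the weights
  m <- max(s$logWt)
  expect_equal(fit$logZ, m + log(sum(exp(s$logWt - m))), tolerance = 1e-10)
  # normalized weights sum to one
  expect_equal(sum(exp(s$logWt - fit$logZ)), 1, tolerance = 1e-10)
  # live points are appended (m >= n beyond the iteration count)
  expect_gte(fit$m, fit$n)
  # evidence lands within its own 3 sigma of the analytic value
  expect_lt(abs(fit$logZ - attr(fit, "logZ_analytic")), 3 * fit$logZ_error)
})

test_that("posterior moments recover the Gaussian location and scale", {
  bm <- gaussian_benchmark(5)
  fit <- ns_gaussian(bm, seed = 19)
  mom <- posterior_moments(fit)
  expect_true(all(abs(mom$mean) < 3 * mom$sd))
  expect_true(all(abs(mom$sd - 1) < 0.2))
})

test_that("information drives the evidence error estimate", {
  bm <- gaussian_benchmark(5)
  fit <- ns_gaussian(bm, seed = 23)
  ie <- information_and_error(fit)
  expect_equal(unname(ie["logZ_error"]), sqrt(unname(ie["H"]) / fit$n))
  # H approximates the prior-to-posterior compression: d * log(w/(sqrt(2*pi*e)))
  expect_equal(unname(ie["H"]), 5 * log(20 / sqrt(2 * pi * exp(1))),
               tolerance = 0.2)
})

test_that("too-narrow priors underestimate the unbounded-prior evidence", {
  bm <- gaussian_benchmark(5, width = 3)
  fit <- ns_gaussian(bm, seed = 2)
  naive <- -5 * log(3)    # pretends all Gaussian mass is inside the box
  expect_lt(fit$logZ, naive)
  # yet agrees with the correctly truncated analytic value
  expect_lt(abs(fit$logZ - gaussian_log_evidence(bm)),
            4 * max(fit$logZ_error, 0.1))
})

test_that("summary, coef and printing expose the fit", {
  bm <- gaussian_benchmark(5)
  fit <- ns_gaussian(bm, seed = 31)
  sm <- summary(fit)
  expect_s3_class(sm, "summary.ns")
  expect_equal(nrow(sm$moments), 5)
  expect_true(!is.unsorted(sm$moments$cv))
  expect_length(coef(fit), 5)
  expect_output(print(fit), "Nested sampling")
  expect_output(print(sm), "active points")
  expect_s3_class(as.data.frame(fit), "data.frame")
})
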