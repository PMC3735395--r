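test_that("transitional log-density matches an independent normal-CDF oracle", {
  # maximum at dY = mu
  expect_equal(transition_logdensity(2.5, mu = 2.5, sigma = 3), 0)
  # degenerate sigma = 0 limit
  expect_equal(transition_logdensity(0, mu = 0, sigma = 0), 0)
  expect_equal(transition_logdensity(1, mu = 0, sigma = 0), -700)
  # independent evaluation of the normalized window ratio
  oracle <- log((pnorm(2.1) - pnorm(1.9)) /
                  (pnorm(0.1) - pnorm(-0.1)))
  expect_equal(transition_logdensity(2, mu = 0, sigma = 1, epsilon = 0.1),
               oracle, tolerance = 1e-12)
  # generic case with non-trivial moments
  mu <- 3.7; s <- 2.2; dY <- -1.4; eps <- 0.25
  oracle2 <- log((pnorm(dY + eps, mu, s) - pnorm(dY - eps, mu, s)) /
                   (pnorm(mu + eps, mu, s) - pnorm(mu - eps, mu, s)))
  expect_equal(transition_logdensity(dY, mu, s, eps), oracle2,
               tolerance = 1e-10)
})

test_that("transitional log-density is stable and <= 0 deep in the tails", {
  v <- transition_logdensity(c(10, 30, 50), mu = 0, sigma = 1)
  expect_true(all(is.finite(v)))
  expect_true(all(diff(v) < 0))     # further out is less likely
  expect_equal(transition_logdensity(1e6, mu = 0, sigma = 1), -700)
  set.seed(1)
  for (k in 1:50) {
    val <- transition_logdensity(rnorm(1, 0, 5), mu = rnorm(1),
                                 sigma = runif(1, 0, 3))
    expect_lte(val, 0)
    expect_gte(val, -700)
  }
})

test_that("drift-consistent endpoints leave the bridge uncorrected", {
  p <- circadian_parameters()
  ds <- drift_series(p, n_obs = 2, interval = 2, l = 20)
  br <- build_bridge(as.numeric(ds[1, 2:4]), as.numeric(ds[2, 2:4]), 0, 2, p)
  expect_equal(unname(br$r), c(1, 1, 1), tolerance = 1e-10)
  # the bridge equals the drift path itself
  path <- drift_propagate(as.numeric(ds[1, 2:4]), 0, 20, 0.1, p)
  expect_equal(unname(br$points), unname(path), tolerance = 1e-8)
})

test_that("end-error correction scales interior points by the printed multiplier", {
  p <- circadian_parameters()
  it <- sample_interval()
  cfg2 <- likelihood_config(bridge_length = 2)
  br <- build_bridge(it$start, it$end, it$t_start, it$interval, p,
                     config = cfg2)
  # uncorrected interior point = one drift step from the start
  raw <- drift_propagate(it$start, it$t_start, 1, it$interval / 2, p)[2, ]
  expect_equal(unname(br$points[2, ]),
               unname(pmax(raw * (1 + (2 - 1) * (br$r - 1) / 2), 0)),
               tolerance = 1e-10)
  # endpoints are pinned to the data
  expect_equal(unname(br$points[1, ]), it$start)
  expect_equal(unname(br$points[3, ]), it$end)
  # default ratio orientation is observed/projected; literal is its inverse
  brl <- build_bridge(it$start, it$end, it$t_start, it$interval, p,
                      config = likelihood_config(bridge_length = 2,
                                                 literal_correction = TRUE))
  expect_equal(unname(brl$r), unname(1 / br$r), tolerance = 1e-10)
})

test_that("interval log-likelihood is a sum of per-step densities, <= 0", {
  p <- circadian_parameters()
  it <- sample_interval()
  steps <- interval_loglik(it$start, it$end, it$t_start, it$interval, p,
                           per_step = TRUE)
  expect_equal(dim(steps), c(20, 3))
  expect_true(all(steps <= 0))
  expect_equal(interval_loglik(it$start, it$end, it$t_start, it$interval, p),
               sum(steps))
  # l = 1: a single transition per species, no interior points
  cfg1 <- likelihood_config(bridge_length = 1)
  s1 <- interval_loglik(it$start, it$end, it$t_start, it$interval, p,
                        config = cfg1, per_step = TRUE)
  expect_equal(dim(s1), c(1, 3))
  bd <- birth_death_rates(it$start, it$t_start, p)
  mu <- (bd[, "beta"] - bd[, "delta"]) * it$interval
  sg <- sqrt((bd[, "beta"] + bd[, "delta"]) * it$interval)
  expect_equal(as.numeric(s1),
               transition_logdensity(it$end - it$start, mu, sg, 0.1),
               tolerance = 1e-10)
})

test_that("dataset log-likelihood is additive over observation intervals", {
  p <- circadian_parameters()
  sp <- sparse_sample(ssa_simulate(p, t_end = 12, seed = 21), 2)
  full <- dataset_loglik(sp, p)
  expect_lt(full, 0)
  k <- 4
  a <- dataset_loglik(sp[1:k, ], p)
  b <- dataset_loglik(sp[k:nrow(sp), ], p)
  expect_equal(a + b, full, tolerance = 1e-9)
  # two observations reduce to a single interval likelihood
  expect_equal(dataset_loglik(sp[1:2, ], p),
               interval_loglik(as.numeric(sp[1, 2:4]),
                               as.numeric(sp[2, 2:4]), sp$time_h[1], 2, p),
               tolerance = 1e-10)
})

test_that("data generated by the drift recursion has log-likelihood zero", {
  p <- circadian_parameters()
  ds <- drift_series(p, n_obs = 4, interval = 2, l = 20)
  expect_equal(dataset_loglik(ds, p), 0, tolerance = 1e-8)
  expect_equal(data_entropy(ds, p), 0, tolerance = 1e-8)
  # and the generating parameters maximize it locally
  worse <- circadian_parameters(vs = 1.7)
  expect_lt(dataset_loglik(ds, worse), -1)
})

test_that("non-uniform sampling derives the step duration per interval", {
  p <- circadian_parameters()
  # drift series at mixed spacings still reconstructs exactly
  path <- drift_propagate(c(400, 250, 150), 0, 60, 0.1, p)
  obs <- data.frame(time_h = c(0, 2, 6),
                    M = path[c(1, 21, 61), 1], Pc = path[c(1, 21, 61), 2],
                    Pn = path[c(1, 21, 61), 3])
  # interval 2 h -> dt 0.1 with l = 20; interval 4 h -> dt 0.2
  cfg <- likelihood_config(bridge_length = 20)
  v1 <- dataset_loglik(obs[1:2, ], p, config = cfg)
  expect_equal(v1, 0, tolerance = 1e-8)
  v2 <- dataset_loglik(obs, p, config = cfg)
  expect_true(is.finite(v2))
})

test_that("equal-sized datasets have approximately equal entropy across spans", {
  p <- circadian_parameters()
  f1 <- ssa_simulate(p, t_end = 24, seed = 31, record_dt = 0.5)
  f3 <- ssa_simulate(p, t_end = 72, seed = 32, record_dt = 0.5)
  s1 <- sparse_sample(f1, 0.5)       # 49 samples over one cycle
  s3 <- sparse_sample(f3, 1.5)       # 49 samples over three cycles
  expect_equal(nrow(s1), 49)
  expect_equal(nrow(s3), 49)
  e1 <- data_entropy(s1, p)
  e3 <- data_entropy(s3, p)
  expect_gt(e1 / e3, 0.7)
  expect_lt(e1 / e3, 1.3)
  # whereas a size-mismatched series has far lower entropy magnitude
  expect_lt(abs(data_entropy(sparse_sample(f1, 2), p)), 0.5 * abs(e1))
})

test_that("entropy of a known single step equals p log p", {
  p <- circadian_parameters()
  it <- sample_interval()
  cfg1 <- likelihood_config(bridge_length = 1)
  lp <- interval_loglik(it$start, it$end, it$t_start, it$interval, p,
                        config = cfg1, per_step = TRUE)
  ts2 <- data.frame(time_h = c(it$t_start, it$t_start + it$interval),
                    M = c(it$start[1], it$end[1]),
                    Pc = c(it$start[2], it$end[2]),
                    Pn = c(it$start[3], it$end[3]))
  expect_equal(data_entropy(ts2, p, config = cfg1),
               sum(exp(lp) * lp), tolerance = 1e-10)
})
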