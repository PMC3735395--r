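test_that("identical seeds give identical stochastic trajectories", {
  p <- circadian_parameters()
  a <- ssa_simulate(p, t_end = 12, seed = 3)
  b <- ssa_simulate(p, t_end = 12, seed = 3)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- ssa_simulate(p, t_end = 12, seed = 4)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("counts stay non-negative integers on the recording grid", {
  ts <- ssa_simulate(circadian_parameters(), t_end = 24, seed = 8)
  m <- as.matrix(as.data.frame(ts)[2:4])
  expect_true(all(m >= 0))
  expect_true(all(m == round(m)))
})

test_that("a near-pure linear death process matches its analytic mean", {
  # isolate mRNA decay: vm/km = 1 with omega large makes delta_M = M,
  # all other channels negligibly slow
  pd <- circadian_parameters(vs = 1e-12, kI = 1, vm = 1, km = 1, ks = 1e-12,
                             vd = 1e-12, kd = 1, k1 = 1e-12, k2 = 1e-12,
                             N = 1, omega = 1e9)
  fin <- vapply(1:1000, function(k)
    as.data.frame(ssa_simulate(pd, t_end = 1, seed = k, record_dt = 1,
                               initial_counts = c(50, 0, 0)))$M[2], 0)
  se <- stats::sd(fin) / sqrt(length(fin))
  expect_lt(abs(mean(fin) - 50 * exp(-1)), 3 * se)
})

test_that("ensemble mean tracks omega times the deterministic trajectory", {
  p <- circadian_parameters()
  det <- simulate_deterministic(p, t_end = 12, output_step = 2,
                                initial_state = default_initial_counts(p) /
                                  p$omega)
  runs <- lapply(1:500, function(k)
    as.matrix(as.data.frame(sparse_sample(
      ssa_simulate(p, t_end = 12, seed = 9000 + k, record_dt = 0.5),
      2))[, 2:4]))
  arr <- simplify2array(runs)
  mu <- apply(arr, c(1, 2), mean)
  se <- apply(arr, c(1, 2), stats::sd) / sqrt(length(runs))
  target <- p$omega * as.matrix(det[, 2:4])
  z <- (mu - target)[-1, ] / se[-1, ]   # t = 0 is the shared initial state
  expect_true(all(abs(z) < 3))
})

test_that("sparse sampling keeps the states on the coarse grid", {
  fine <- ssa_simulate(circadian_parameters(), t_end = 24, seed = 5)
  sp <- sparse_sample(fine, 2)
  expect_equal(nrow(sp), 13)
  expect_equal(sp$time_h, seq(0, 24, by = 2))
  expect_equal(as.data.frame(sp)[1, ], as.data.frame(fine)[1, ])
  # identity when the interval equals the fine resolution
  expect_equal(nrow(sparse_sample(fine, 0.1)), nrow(fine))
  # 5 cycles at 2 h -> 61 points
  fine5 <- ssa_simulate(circadian_parameters(), t_end = 120, seed = 6)
  expect_equal(nrow(sparse_sample(fine5, 2)), 61)
  expect_error(sparse_sample(fine, 0.15), "multiple")
})

test_that("dataset generation follows the replicate design with distinct seeds", {
  p <- circadian_parameters()
  ds <- generate_dataset(p, cycles_list = 1:2, replicates = 2, base_seed = 7,
                         record_dt = 0.5)
  expect_length(ds, 4)
  expect_named(ds, c("DD_c1_r1", "DD_c1_r2", "DD_c2_r1", "DD_c2_r2"))
  expect_equal(nrow(ds$DD_c1_r1), 13)
  expect_equal(attr(ds$DD_c2_r2, "cycles"), 2)
  # distinct (condition, cycles, replicate) triples -> distinct seeds
  grid <- expand.grid(cond = c("DD", "LD"), cyc = 1:5, rep = 1:5)
  seeds <- mapply(derive_seed, 1, grid$cond, grid$cyc, grid$rep)
  expect_equal(anyDuplicated(seeds), 0)
  expect_true(all(seeds > 0 & seeds < 2^31))
  # regenerating with the same base seed reproduces the data exactly
  ds2 <- generate_dataset(p, cycles_list = 1:2, replicates = 2, base_seed = 7,
                          record_dt = 0.5)
  expect_identical(as.data.frame(ds$DD_c2_r1), as.data.frame(ds2$DD_c2_r1))
})

test_that("LD datasets encode the daylength in the protocol", {
  conds <- list(LD6 = light_protocol("LD", 0.8, 0, 6),
                LD18 = light_protocol("LD", 0.8, 0, 18))
  ds <- generate_dataset(circadian_parameters(), conds, cycles_list = 1,
                         replicates = 1, base_seed = 3, record_dt = 0.5)
  expect_equal(attr(ds$LD6_c1_r1, "protocol")$t_dusk, 6)
  expect_equal(attr(ds$LD18_c1_r1, "protocol")$t_dusk, 18)
})

test_that("time series round-trip through CSV plus sidecar", {
  ts <- sparse_sample(ssa_simulate(circadian_parameters(), t_end = 24,
                                   seed = 12), 2)
  path <- file.path(tempdir(), "ts-roundtrip.csv")
  write_timeseries(ts, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_timeseries(path)
  expect_equal(as.data.frame(back), as.data.frame(ts))
  expect_equal(attr(back, "omega"), 500)
  expect_equal(attr(back, "protocol")$mode, "DD")
  expect_equal(attr(back, "params")$vs, 1.6)
  unlink(c(path, paste0(path, ".json")))
})
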