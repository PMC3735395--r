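# Shared fixtures: everything is generated in code at test time.

# Observations lying exactly on the drift recursion (the most likely path),
# spaced `interval` hours apart, so the bridge reconstruction is exact and
# the transitional log-likelihood is identically zero.
drift_series <- function(params, n_obs = 3, interval = 2, l = 20,
                         start = c(400, 250, 150),
                         protocol = light_protocol("DD")) {
  path <- drift_propagate(start, 0, (n_obs - 1) * l, interval / l, params,
                          protocol)
  idx <- seq(1, nrow(path), by = l)
  data.frame(time_h = (seq_len(n_obs) - 1) * interval,
             M = path[idx, 1], Pc = path[idx, 2], Pn = path[idx, 3])
}

# One sparsely-sampled stochastic interval reused by bridge tests.
sample_interval <- function(seed = 11, index = 4) {
  p <- circadian_parameters()
  sp <- sparse_sample(ssa_simulate(p, t_end = 24, seed = seed), 2)
  list(params = p,
       start = as.numeric(sp[index, c("M", "Pc", "Pn")]),
       end = as.numeric(sp[index + 1, c("M", "Pc", "Pn")]),
       t_start = sp$time_h[index], interval = 2)
}
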