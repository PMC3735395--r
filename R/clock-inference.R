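#' Default prior for the nine free clock parameters
#'
#' Uniform on [0.05, 2.5] in each parameter's native units, identical
#' across DD and LD conditions and across Hill-coefficient variants so
#' that evidences are comparable.  Bounds are strictly positive (a zero
#' rate would remove its reaction from the model) and wide enough that
#' every posterior is unimodal within the box; see the methods vignette
#' for how the box was chosen.
#'
#' @param lower,upper common bounds, or length-9 vectors for per-parameter
#'   overrides.
#' @return A \code{\link{uniform_prior}} over the nine free parameters.
#' @export
default_clock_prior <- function(lower = 0.05, upper = 2.5) {
  nm <- free_parameter_names()
  uniform_prior(rep_len(lower, 9), rep_len(upper, 9), nm)
}

#' Transitional log-likelihood as a function of the free parameters
#'
#' Builds the closure passed to \code{\link{nested_sampling}}: the nine
#' kinetic constants vary; the Hill coefficient and system size stay
#' fixed.
#'
#' @param ts a \code{"clock_ts"} of sparse counts.
#' @param protocol a \code{\link{light_protocol}}; defaults to the series'
#'   own protocol metadata.
#' @param config a \code{\link{likelihood_config}}.
#' @param N fixed Hill coefficient (default 4).
#' @param omega fixed system size (default 500).
#' @return function(theta) -> log-likelihood, theta ordered as
#'   \code{\link{free_parameter_names}}.
#' @export
clock_loglik <- function(ts, protocol = NULL, config = likelihood_config(),
                         N = 4, omega = 500) {
  if (is.null(protocol)) protocol <- attr(ts, "protocol")
  if (is.null(protocol)) protocol <- light_protocol("DD")
  times <- as.numeric(ts$time_h)
  counts <- ts_matrix(ts)
  pv <- c(rep(NA_real_, 9), N, omega)
  prot <- prot_vec(protocol)
  eps <- config$epsilon
  l <- config$bridge_length
  lit <- config$literal_correction
  flo <- config$floor
  function(theta) {
    pv[1:9] <- theta
    cpp_dataset_loglik(times, counts, pv, prot, eps, l, lit, flo)
  }
}

#' Infer clock parameters by nested sampling
#'
#' Runs nested sampling with the transitional (bridging) likelihood on a
#' sparse count series.  Nine kinetic constants are integrated; the Hill
#' coefficient N and the system size omega are held fixed.  The summary
#' orders parameters by posterior coefficient of variation, most to least
#' constrained.
#'
#' @inheritParams clock_loglik
#' @param prior a \code{\link{uniform_prior}} over the nine free
#'   parameters.
#' @param n active points (default 25).
#' @param seed optional integer seed.
#' @param ... further arguments to \code{\link{nested_sampling}}.
#' @return An object of class \code{c("clock_ns", "ns")}.
#' @export
clock_infer <- function(ts, prior = default_clock_prior(), protocol = NULL,
                        config = likelihood_config(), N = 4, omega = 500,
                        n = 25, seed = NULL, ...) {
  stopifnot(prior$d == 9)
  if (is.null(protocol)) protocol <- attr(ts, "protocol")
  if (is.null(protocol)) protocol <- light_protocol("DD")
  ll <- clock_loglik(ts, protocol, config, N = N, omega = omega)
  fit <- nested_sampling(ll, prior, n = n, seed = seed, ...)
  fit$N <- N
  fit$omega <- omega
  fit$protocol <- protocol
  fit$config <- config
  class(fit) <- c("clock_ns", "ns")
  fit
}

#' @export
print.clock_ns <- function(x, ...) {
  cat(sprintf("Clock parameter inference (N = %d fixed, omega = %g, %s)\n",
              x$N, x$omega, x$protocol$mode))
  NextMethod()
}

#' Posterior-mean parameter set of a clock fit
#'
#' @param fit a \code{"clock_ns"} object.
#' @return A \code{\link{circadian_parameters}} object at the posterior
#'   means with the fit's fixed N and omega.
#' @export
clock_map_parameters <- function(fit) {
  stopifnot(inherits(fit, "clock_ns"))
  mm <- coef(fit)
  do.call(circadian_parameters,
          c(as.list(mm[free_parameter_names()]),
            list(N = fit$N, omega = fit$omega)))
}

#' Simulate new data from a fitted clock model
#'
#' Stochastic realisations at the posterior-mean parameters, matching the
#' fitted series' span and sampling interval.
#'
#' @param object a \code{"clock_ns"} fit.
#' @param nsim number of realisations.
#' @param seed optional seed.
#' @param t_end,interval span and sampling interval (h); defaults 120 and 2.
#' @param ... unused.
#' @return A list of \code{"clock_ts"} objects.
#' @export
simulate.clock_ns <- function(object, nsim = 1, seed = NULL, t_end = 120,
                              interval = 2, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- clock_map_parameters(object)
  lapply(seq_len(nsim), function(i)
    sparse_sample(ssa_simulate(p, object$protocol, t_end = t_end), interval))
}

#' Hill-coefficient model selection
#'
#' Treats integer Hill coefficients as alternative models: one nested
#' sampling run per value of N under a common prior, compared by log
#' marginal likelihood.  Three or more cycles of data are typically
#' needed to recover the generating coefficient decisively.
#'
#' @inheritParams clock_infer
#' @param N_values Hill coefficients to compare (default 2:5).
#' @param base_seed seed from which per-model seeds are derived.
#' @return A \code{\link{compare_models}} object with the individual fits
#'   attached as attribute \code{"fits"}.
#' @export
clock_select <- function(ts, N_values = 2:5, prior = default_clock_prior(),
                         protocol = NULL, config = likelihood_config(),
                         omega = 500, n = 25, base_seed = 1, ...) {
  fits <- lapply(N_values, function(Nv)
    clock_infer(ts, prior, protocol, config, N = Nv, omega = omega, n = n,
                seed = derive_seed(base_seed, "select", Nv, 1), ...))
  names(fits) <- paste0("N=", N_values)
  cmp <- compare_models(vapply(fits, `[[`, 0, "logZ"),
                        vapply(fits, `[[`, 0, "logZ_error"))
  attr(cmp, "fits") <- fits
  cmp
}
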