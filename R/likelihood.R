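#' Configuration of the transitional (bridging) likelihood
#'
#' @param epsilon half-width of the density window around each increment,
#'   in counts; default 0.1.
#' @param bridge_length number of short steps l per observation interval;
#'   default 20 (the step duration is the observation interval
#'   divided by l).
#' @param literal_correction if \code{TRUE}, the bridge end-error ratio is
#'   taken as projected/observed, i.e. the printed form; the default
#'   \code{FALSE} uses observed/projected, which makes the corrected path
#'   terminate at the observed endpoint.  See the methods vignette.
#' @param floor lower bound on each per-step log-density (default -700),
#'   keeping totals finite and orderable by the sampler.
#' @return An object of class \code{"likelihood_config"}.
#' @export
likelihood_config <- function(epsilon = 0.1, bridge_length = 20,
                              literal_correction = FALSE, floor = -700) {
  stopifnot(epsilon > 0, bridge_length >= 1,
            bridge_length == round(bridge_length), floor < 0)
  structure(list(epsilon = epsilon, bridge_length = as.integer(bridge_length),
                 literal_correction = isTRUE(literal_correction),
                 floor = floor), class = "likelihood_config")
}

#' Normalized transitional log-density of a count increment
#'
#' The increment of a birth-death process over a short interval is
#' approximately normal with mean mu = (beta - delta) * dT and variance
#' (beta + delta) * dT.  The density of an observed increment dY is taken
#' as the probability mass of a window of half-width epsilon, divided by
#' the mass of the same window centred on the mean, so the log value is
#' always <= 0 with equality iff dY = mu.  This normalisation prevents the
#' variance-minimisation bias that an unnormalised window density suffers
#' on correlated stochastic data.
#'
#' @param dY observed increment(s) (counts); vectorized.
#' @param mu,sigma transition moments (recycled against \code{dY}).
#' @param epsilon window half-width (counts).
#' @param floor lower bound on the log-density.
#' @return Log-density value(s) <= 0.  The degenerate case sigma = 0
#'   returns 0 when |dY - mu| < epsilon and \code{floor} otherwise.
#' @examples
#' transition_logdensity(0, mu = 0, sigma = 1)  # 0
#' @export
transition_logdensity <- function(dY, mu, sigma, epsilon = 0.1,
                                  floor = -700) {
  stopifnot(epsilon > 0, all(sigma >= 0))
  cpp_trans_logdens(as.numeric(dY), as.numeric(mu), as.numeric(sigma),
                    epsilon, floor)
}

#' Build the bridge between two sparse observations
#'
#' Interior points are generated by the deterministic drift recursion
#' B[i+1] = B[i] + (beta(B[i]) - delta(B[i])) * dT starting from the
#' observed start state; the endpoint projected from B[l] defines a
#' per-species end error, which is assigned proportionally along the path
#' by multiplying B[i] by (1 + (i - 1)(r - 1)/l).  When the drift already
#' reproduces the observed endpoint, r = 1 and the bridge is unchanged.
#' Corrected points are floored at zero.
#'
#' @param start,end observed count vectors \code{c(M, Pc, Pn)}.
#' @param t_start time of the start observation (h).
#' @param interval time between the observations (h).
#' @param params a \code{\link{circadian_parameters}} object.
#' @param protocol a \code{\link{light_protocol}}.
#' @param config a \code{\link{likelihood_config}}.
#' @return A list of class \code{"clock_bridge"}: \code{points}
#'   ((l+1) x 3 matrix, rows from start to end), \code{end_projection}
#'   (uncorrected projected endpoint), \code{r} (per-species correction
#'   ratios), plus the step duration \code{dt}.
#' @export
build_bridge <- function(start, end, t_start, interval, params,
                         protocol = light_protocol("DD"),
                         config = likelihood_config()) {
  stopifnot(length(start) == 3, length(end) == 3, all(start >= 0),
            all(end >= 0), interval > 0)
  l <- config$bridge_length
  dt <- interval / l
  out <- cpp_build_bridge(as.numeric(start), as.numeric(end), t_start, dt, l,
                          par_vec(params), prot_vec(protocol),
                          config$literal_correction)
  if (any(!is.finite(out$end_projection)))
    stop("non-finite bridge projection")
  colnames(out$points) <- c("M", "Pc", "Pn")
  names(out$end_projection) <- names(out$r) <- c("M", "Pc", "Pn")
  structure(c(out, list(t_start = t_start, dt = dt)),
            class = "clock_bridge")
}

#' Log-likelihood of one observation interval
#'
#' Sum over the l bridge steps and the three species of the normalized
#' transitional log-density, where the moments at each step are recomputed
#' from the (corrected) predecessor point.
#'
#' @inheritParams build_bridge
#' @param per_step if \code{TRUE} return the l x 3 matrix of per-step
#'   log-densities instead of their sum.
#' @return A scalar log-likelihood <= 0 (or a matrix if \code{per_step}).
#' @export
interval_loglik <- function(start, end, t_start, interval, params,
                            protocol = light_protocol("DD"),
                            config = likelihood_config(), per_step = FALSE) {
  l <- config$bridge_length
  steps <- cpp_interval_steps(as.numeric(start), as.numeric(end), t_start,
                              interval / l, l, par_vec(params),
                              prot_vec(protocol), config$epsilon,
                              config$literal_correction, config$floor)
  if (per_step) {
    colnames(steps) <- c("M", "Pc", "Pn")
    steps
  } else sum(steps)
}

ts_matrix <- function(ts) {
  m <- as.matrix(as.data.frame(ts)[c("M", "Pc", "Pn")])
  storage.mode(m) <- "double"
  m
}

#' Total transitional log-likelihood of a sparse time series
#'
#' Sum of \code{\link{interval_loglik}} over the m - 1 observation
#' intervals; the model likelihood is the product over species and
#' intervals.  The step duration is derived per interval from the actual
#' time stamps, so non-uniform sampling is supported.
#'
#' @param ts a \code{"clock_ts"} (or data frame with columns
#'   \code{time_h, M, Pc, Pn}).
#' @inheritParams build_bridge
#' @return Scalar log-likelihood (finite; per-step values are floored).
#' @export
dataset_loglik <- function(ts, params, protocol = light_protocol("DD"),
                           config = likelihood_config()) {
  stopifnot(nrow(ts) >= 2)
  cpp_dataset_loglik(as.numeric(ts$time_h), ts_matrix(ts), par_vec(params),
                     prot_vec(protocol), config$epsilon,
                     config$bridge_length, config$literal_correction,
                     config$floor)
}

#' Entropy of a dataset under the generating model
#'
#' Sum of p log(p) over all bridge-step probabilities p (the normalized
#' transitional densities).  Used to compare the information content of
#' datasets with different spans and sampling intervals: keeping the
#' number of samples constant approximately equalises the entropy.
#'
#' @inheritParams dataset_loglik
#' @return Scalar entropy (<= 0); steps with p = 0 contribute 0.
#' @export
data_entropy <- function(ts, params, protocol = light_protocol("DD"),
                         config = likelihood_config()) {
  stopifnot(nrow(ts) >= 2)
  cpp_dataset_entropy(as.numeric(ts$time_h), ts_matrix(ts), par_vec(params),
                      prot_vec(protocol), config$epsilon,
                      config$bridge_length, config$literal_correction,
                      config$floor)
}

#' Propagate a state by the drift recursion
#'
#' Repeated application of the expected increment
#' (beta - delta) * dT; the most likely (deterministic) evolution used to
#' seed bridges, exposed for generating drift-consistent test data.
#'
#' @param start count vector \code{c(M, Pc, Pn)}.
#' @param t_start start time (h).
#' @param n_steps number of drift steps.
#' @param dt step duration (h).
#' @inheritParams build_bridge
#' @return Matrix of n_steps + 1 states (rows), starting at \code{start}.
#' @export
drift_propagate <- function(start, t_start, n_steps, dt, params,
                            protocol = light_protocol("DD")) {
  out <- matrix(0, n_steps + 1, 3, dimnames = list(NULL, c("M", "Pc", "Pn")))
  out[1, ] <- start
  x <- as.numeric(start)
  for (i in seq_len(n_steps)) {
    r <- cpp_bd_rates(x, t_start + (i - 1) * dt, par_vec(params),
                      prot_vec(protocol))
    x <- pmax(x + (r[, 1] - r[, 2]) * dt, 0)
    out[i + 1, ] <- x
  }
  out
}
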