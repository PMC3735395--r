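#' Gaussian benchmark with analytic evidence
#'
#' A d-dimensional isotropic Gaussian likelihood under a centred uniform
#' box prior of width \code{width} standard deviations per dimension: the
#' standard calibration problem for which the evidence is available in
#' closed form.
#'
#' @param d dimension (the calibration suite uses 5, 10, 20, 30).
#' @param sigma per-dimension standard deviation.
#' @param width prior width in multiples of sigma (default 20).
#' @return An object of class \code{"gaussian_benchmark"}.
#' @export
gaussian_benchmark <- function(d, sigma = 1, width = 20) {
  stopifnot(d >= 1, sigma > 0, width > 0)
  structure(list(d = d, sigma = sigma, width = width,
                 prior = uniform_prior(rep(-width * sigma / 2, d),
                                       rep(width * sigma / 2, d),
                                       paste0("theta", seq_len(d)))),
            class = "gaussian_benchmark")
}

#' Gaussian benchmark log-likelihood
#'
#' @param theta parameter vector of length d.
#' @param benchmark a \code{\link{gaussian_benchmark}}.
#' @return Sum of the d independent normal log-densities.
#' @export
gaussian_loglik <- function(theta, benchmark) {
  s <- benchmark$sigma
  -0.5 * benchmark$d * log(2 * pi * s^2) - 0.5 * sum(theta^2) / s^2
}

#' Analytic log-evidence of a Gaussian benchmark
#'
#' Per dimension the evidence is the Gaussian mass inside the prior box
#' divided by the box width; dimensions multiply.  Exact for the truncated
#' uniform prior, hence an exact oracle for nested sampling estimates.
#'
#' @param benchmark a \code{\link{gaussian_benchmark}}.
#' @return Scalar analytic logZ.
#' @examples
#' gaussian_log_evidence(gaussian_benchmark(1, 1, 20))  # ~ -log(20)
#' @export
gaussian_log_evidence <- function(benchmark) {
  w <- benchmark$width
  s <- benchmark$sigma
  benchmark$d * (log(2 * stats::pnorm(w / 2) - 1) - log(w * s))
}

#' Run nested sampling on a Gaussian benchmark
#'
#' @param benchmark a \code{\link{gaussian_benchmark}}.
#' @param n active points (default 25).
#' @param seed optional seed.
#' @param ... further arguments to \code{\link{nested_sampling}}.
#' @return An \code{"ns"} fit with the analytic evidence attached as
#'   attribute \code{"logZ_analytic"}.
#' @export
ns_gaussian <- function(benchmark, n = 25, seed = NULL, ...) {
  fit <- nested_sampling(function(th) gaussian_loglik(th, benchmark),
                         benchmark$prior, n = n, seed = seed, ...)
  attr(fit, "logZ_analytic") <- gaussian_log_evidence(benchmark)
  fit
}

#' Repeated Gaussian calibration runs
#'
#' Seeded repeats of \code{\link{ns_gaussian}} across dimensions,
#' collecting the evidence estimate, its analytic target, the information
#' and the likelihood-evaluation effort; the instrument behind the
#' evidence-recovery and step-adaptation efficiency checks.
#'
#' @param d_values dimensions to test.
#' @param runs seeded runs per dimension.
#' @param n active points.
#' @param sigma,width benchmark geometry.
#' @param base_seed seed for run (d, k) is derived stably from this.
#' @param adapt enable step-size adaptation.
#' @param ... further arguments to \code{\link{nested_sampling}}.
#' @return Data frame with one row per run: d, run, logZ, logZ_analytic,
#'   logZ_error, H, n_evals, within3 (inside 3 sqrt(H/n) of the truth).
#' @export
gaussian_suite <- function(d_values = c(5, 10, 20, 30), runs = 30, n = 25,
                           sigma = 1, width = 20, base_seed = 1,
                           adapt = TRUE, ...) {
  rows <- list()
  for (d in d_values) {
    bm <- gaussian_benchmark(d, sigma, width)
    for (k in seq_len(runs)) {
      fit <- ns_gaussian(bm, n = n,
                         seed = derive_seed(base_seed, "gauss", d, k),
                         adapt = adapt, ...)
      rows[[length(rows) + 1]] <- data.frame(
        d = d, run = k, logZ = fit$logZ,
        logZ_analytic = attr(fit, "logZ_analytic"),
        logZ_error = fit$logZ_error, H = fit$H, n_evals = fit$n_evals,
        within3 = abs(fit$logZ - attr(fit, "logZ_analytic")) <=
          3 * fit$logZ_error)
    }
  }
  do.call(rbind, rows)
}

#' Simulated-annealing search for the optimal bridge
#'
#' Independent oracle for the bridge heuristic: maximizes the path
#' log-likelihood of one observation interval over the (l - 1) x 3 free
#' interior coordinates by annealed per-coordinate Gaussian perturbation
#' (geometric cooling), starting from linear interpolation between the
#' observed endpoints.  Returns the best value found over \code{repeats}
#' seeded restarts.
#'
#' @inheritParams build_bridge
#' @param l bridge length (default 10, a 27-dimensional search for three
#'   species).
#' @param n_sweeps annealing sweeps per restart (default 500).
#' @param t0 initial temperature.
#' @param cool geometric cooling factor per sweep.
#' @param prop_frac proposal standard deviation as a fraction of each
#'   species' scale.
#' @param repeats independent restarts; the best value is returned.
#' @param seed optional seed.
#' @return Best path log-likelihood found.
#' @export
sa_optimize_bridge <- function(start, end, t_start, interval, params,
                               protocol = light_protocol("DD"),
                               config = likelihood_config(), l = 10,
                               n_sweeps = 500, t0 = 1, cool = 0.95,
                               prop_frac = 0.05, repeats = 1, seed = NULL) {
  stopifnot(l >= 2, repeats >= 1)
  if (!is.null(seed)) set.seed(seed)
  best <- -Inf
  for (r in seq_len(repeats)) {
    v <- cpp_sa_bridge(as.numeric(start), as.numeric(end), t_start,
                       interval / l, l, par_vec(params), prot_vec(protocol),
                       config$epsilon, config$floor, n_sweeps, t0, cool,
                       prop_frac)
    if (v > best) best <- v
  }
  best
}

#' Heuristic-versus-annealing bridge agreement
#'
#' Displaces the end observation of one interval over a factorial grid of
#' per-species relative displacements, computes the bridge-heuristic
#' log-likelihood and the best of \code{repeats} simulated-annealing
#' optimisations at each grid point, and reports their Pearson
#' correlation.
#'
#' @inheritParams sa_optimize_bridge
#' @param displacements relative displacements applied per species (the
#'   grid is the full factorial over the three species); e.g.
#'   \code{c(-0.10, -0.05, 0.05, 0.10)}.
#' @return List: \code{grid} data frame (displacement factors, heuristic
#'   and SA log-likelihoods) and \code{correlation}.
#' @export
bridge_sa_correlation <- function(start, end, t_start, interval, params,
                                  protocol = light_protocol("DD"),
                                  config = likelihood_config(), l = 10,
                                  displacements = c(-0.10, -0.05, 0.05, 0.10),
                                  repeats = 10, n_sweeps = 500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(fM = displacements, fPc = displacements,
                      fPn = displacements)
  heur <- sa <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    end_g <- pmax(as.numeric(end) * (1 + as.numeric(grid[g, ])), 0)
    heur[g] <- interval_loglik(start, end_g, t_start, interval, params,
                               protocol,
                               likelihood_config(config$epsilon, l,
                                                 config$literal_correction,
                                                 config$floor))
    sa[g] <- sa_optimize_bridge(start, end_g, t_start, interval, params,
                                protocol, config, l = l,
                                n_sweeps = n_sweeps, repeats = repeats)
  }
  grid$heuristic <- heur
  grid$annealed <- sa
  list(grid = grid, correlation = stats::cor(heur, sa))
}

#' Compare models by log marginal likelihood
#'
#' Re-zeroes the logZ values to the per-series maximum, forms pairwise log
#' Bayes factors under equal prior model probabilities, and flags the
#' comparison as indistinguishable when the margin between the best and
#' second-best model is within their combined logZ uncertainty (one
#' standard deviation).
#'
#' @param logZ named numeric vector of log-evidences (one per model).
#' @param logZ_error matching vector of logZ uncertainties.
#' @return An object of class \code{"model_comparison"}: data frame
#'   \code{table} (label, logZ, error, logZ re-zeroed), matrix
#'   \code{log_bayes_factors}, \code{best}, \code{margin},
#'   \code{indistinguishable}.
#' @export
compare_models <- function(logZ, logZ_error = rep(0, length(logZ))) {
  stopifnot(length(logZ) >= 2, length(logZ_error) == length(logZ))
  labels <- names(logZ)
  if (is.null(labels)) labels <- paste0("model", seq_along(logZ))
  tab <- data.frame(label = labels, logZ = as.numeric(logZ),
                    logZ_error = as.numeric(logZ_error),
                    logZ_rezeroed = as.numeric(logZ) - max(logZ))
  bf <- outer(as.numeric(logZ), as.numeric(logZ), "-")
  dimnames(bf) <- list(labels, labels)
  ord <- order(logZ, decreasing = TRUE)
  margin <- logZ[ord[1]] - logZ[ord[2]]
  comb <- sqrt(logZ_error[ord[1]]^2 + logZ_error[ord[2]]^2)
  structure(list(table = tab, log_bayes_factors = bf,
                 best = labels[ord[1]], margin = as.numeric(margin),
                 combined_error = comb,
                 indistinguishable = margin < comb),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison by log marginal likelihood:\n")
  print(transform(x$table, logZ = round(logZ, 3),
                  logZ_error = round(logZ_error, 3),
                  logZ_rezeroed = round(logZ_rezeroed, 3)))
  cat(sprintf("Best: %s (margin %.3f over second best%s)\n", x$best,
              x$margin,
              if (x$indistinguishable) "; within one combined sd" else ""))
  invisible(x)
}
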