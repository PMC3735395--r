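#' Overflow-safe log(e^a + e^b)
#'
#' @param a,b log-scale values (may be -Inf).
#' @return log(exp(a) + exp(b)).
#' @examples
#' log_plus(log(1), log(3))  # log(4)
#' @export
log_plus <- function(a, b) {
  if (a == -Inf) return(b)
  if (b == -Inf) return(a)
  m <- pmax(a, b)
  m + log1p(exp(pmin(a, b) - m))
}

#' Uniform box prior with strictly positive bounds support
#'
#' The prior used throughout: independent uniform densities between fixed
#' lower and upper limits in each parameter's native units.  Rate
#' constants take strictly positive lower limits (a zero rate would
#' remove the reaction from the model).
#'
#' @param lower,upper numeric vectors of bounds (equal length).
#' @param names optional parameter names.
#' @return An object of class \code{"uniform_prior"}.
#' @examples
#' uniform_prior(rep(0.05, 9), rep(5, 9), free_parameter_names())
#' @export
uniform_prior <- function(lower, upper, names = NULL) {
  stopifnot(length(lower) == length(upper), all(lower < upper))
  if (!is.null(names)) {
    stopifnot(length(names) == length(lower))
    names(lower) <- names(upper) <- names
  }
  structure(list(lower = lower, upper = upper, d = length(lower)),
            class = "uniform_prior")
}

#' @export
print.uniform_prior <- function(x, ...) {
  cat(sprintf("Uniform prior over %d dimensions:\n", x$d))
  print(data.frame(lower = x$lower, upper = x$upper))
  invisible(x)
}

prior_sample <- function(prior) {
  stats::runif(prior$d, prior$lower, prior$upper)
}

#' Draw the initial population of active points
#'
#' @param n number of active points.
#' @param prior a \code{\link{uniform_prior}}.
#' @param loglik log-likelihood function.
#' @param initial_step_frac initial step size as a fraction of each prior
#'   width (default 0.1).
#' @return List of n active points (theta, logL, step_sizes).
#' @export
initialize_points <- function(n, prior, loglik, initial_step_frac = 0.1) {
  stopifnot(n >= 1)
  width <- prior$upper - prior$lower
  pts <- lapply(seq_len(n), function(i) {
    th <- prior_sample(prior)
    new_active_point(th, loglik(th), initial_step_frac * width)
  })
  if (all(!is.finite(vapply(pts, `[[`, 0, "logL"))))
    stop("no finite log-likelihood anywhere in the initial population")
  pts
}

#' Stopping rule for nested sampling
#'
#' The weight assigned to successive discarded points eventually decays at
#' the pure prior-shrinkage rate: over a window of w iterations the log
#' width falls by exactly w/n.  Sampling terminates once the observed fall
#' in logWt over the window is within \code{tol} of w/n (so likelihood
#' growth no longer contributes) and the current likelihood threshold
#' exceeds the current weight by at least \code{margin} log units (which
#' prevents early termination), or when the posterior-sample cap is hit.
#'
#' @param logWt_hist numeric vector of logWt values up to iteration i.
#' @param logLstar current likelihood threshold.
#' @param i current iteration.
#' @param n number of active points.
#' @param window comparison lag in iterations (default 50).
#' @param tol tolerance on (window/n - observed fall) (default 0.005).
#' @param margin required excess of logLstar over current logWt.
#' @param max_posterior cap on the number of posterior points.
#' @return List \code{stop} (logical) and \code{reason} (character).
#' @export
stopping_check <- function(logWt_hist, logLstar, i, n, window = 50,
                           tol = 0.005, margin = 10,
                           max_posterior = Inf) {
  if (i >= max_posterior)
    return(list(stop = TRUE, reason = "posterior cap"))
  if (i <= window) return(list(stop = FALSE, reason = "history too short"))
  fall <- logWt_hist[i - window] - logWt_hist[i]
  if ((window / n - fall) <= tol && (logLstar - logWt_hist[i]) >= margin)
    return(list(stop = TRUE, reason = "logWt width test"))
  list(stop = FALSE, reason = "continuing")
}

#' Nested sampling
#'
#' Computes the Bayesian evidence Z = integral of likelihood over the
#' prior, together with a weighted posterior sample, by maintaining a
#' population of n active points under a rising likelihood constraint.
#' On each iteration the worst point is discarded (becoming a posterior
#' sample with weight L_i * dX_i, where the enclosed prior mass X shrinks
#' geometrically by Beta(n, 1)-distributed ratios), and replaced by a new
#' point drawn uniformly from the prior subject to L > L*, found by
#' stepping-out slice sampling seeded at a randomly chosen survivor.
#'
#' @param loglik function(theta) -> log-likelihood.
#' @param prior a \code{\link{uniform_prior}}.
#' @param n number of active points (default 25, sufficient for evidence
#'   integration in up to 30 dimensions under adequately wide priors).
#' @param max_posterior cap on posterior points (default 100 * n).
#' @param window,tol,margin stopping-rule controls, see
#'   \code{\link{stopping_check}}.
#' @param n_passes slice-sampling sweeps per replacement (default 1).
#' @param adapt self-tune slice step sizes (default TRUE).
#' @param threshold step-size adaptation threshold.
#' @param invert_adaptation see \code{\link{adapt_step_size}}.
#' @param initial_step_frac initial step sizes as a fraction of the prior
#'   widths.
#' @param add_final include the final active population in the evidence
#'   (mean remaining likelihood times remaining width) and in the
#'   posterior sample (default TRUE).
#' @param seed optional integer seed (all randomness flows from R's RNG).
#' @param verbose print progress every 100 iterations.
#' @return An object of class \code{"ns"}: list with \code{logZ},
#'   \code{logZ_error}, \code{H} (information), \code{samples} (data frame
#'   of posterior points: iteration, parameters, logL, logWt),
#'   \code{n}, \code{m}, \code{n_evals}, \code{termination}, \code{seed}.
#' @examples
#' pr <- uniform_prior(-10, 10, "x")
#' fit <- nested_sampling(function(th) dnorm(th, log = TRUE), pr,
#'                        n = 25, seed = 1)
#' summary(fit)
#' @export
nested_sampling <- function(loglik, prior, n = 25,
                            max_posterior = 100 * n, window = 50,
                            tol = 0.005, margin = 10, n_passes = 1,
                            adapt = TRUE, threshold = 3,
                            invert_adaptation = TRUE,
                            initial_step_frac = 0.1, add_final = TRUE,
                            seed = NULL, verbose = FALSE) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  pts <- initialize_points(n, prior, loglik, initial_step_frac)
  n_evals <- n
  d <- prior$d
  cap <- max_posterior + n * as.integer(add_final) + 8L
  theta_mat <- matrix(NA_real_, cap, d)
  logL_vec <- numeric(cap)
  logWt_vec <- numeric(cap)
  logZ <- -Inf
  i <- 0L
  termination <- "posterior cap"
  repeat {
    i <- i + 1L
    logLs <- vapply(pts, `[[`, 0, "logL")
    worst <- which.min(logLs)          # which.min: ties -> lowest index
    logLstar <- logLs[worst]
    log_width <- log((exp(-(i - 1) / n) - exp(-(i + 1) / n)) / 2)
    logWt <- log_width + logLstar
    logZ <- log_plus(logZ, logWt)
    theta_mat[i, ] <- pts[[worst]]$theta
    logL_vec[i] <- logLstar
    logWt_vec[i] <- logWt
    chk <- stopping_check(logWt_vec, logLstar, i, n, window, tol, margin,
                          max_posterior)
    if (chk$stop) { termination <- chk$reason; break }
    seed_idx <- if (n == 1) 1L else sample(seq_len(n)[-worst], 1)
    new_pt <- tryCatch(
      slice_explore(pts[[seed_idx]], logLstar, prior, loglik, n_passes,
                    adapt, threshold, invert_adaptation),
      error = function(e)
        stop("exploration failed at iteration ", i, ": ",
             conditionMessage(e)))
    n_evals <- n_evals + new_pt$n_evals
    pts[[worst]] <- new_pt
    if (verbose && i %% 100 == 0)
      message(sprintf("iter %d  logZ %.3f  logL* %.3f", i, logZ, logLstar))
  }
  m <- i
  if (add_final) {
    # remaining prior mass spread evenly over the live points, appended in
    # ascending likelihood order to preserve the monotone logL sequence
    log_rem <- -i / n - log(n)
    ord <- order(vapply(pts, `[[`, 0, "logL"))
    for (j in ord) {
      m <- m + 1L
      theta_mat[m, ] <- pts[[j]]$theta
      logL_vec[m] <- pts[[j]]$logL
      logWt_vec[m] <- log_rem + pts[[j]]$logL
      logZ <- log_plus(logZ, logWt_vec[m])
    }
  }
  samples <- data.frame(iteration = seq_len(m),
                        theta_mat[seq_len(m), , drop = FALSE],
                        logL = logL_vec[seq_len(m)],
                        logWt = logWt_vec[seq_len(m)])
  pn <- names(prior$lower)
  if (is.null(pn)) pn <- paste0("theta", seq_len(d))
  names(samples)[2:(d + 1)] <- pn
  res <- structure(list(logZ = logZ, samples = samples, n = n, m = m,
                        n_evals = n_evals, termination = termination,
                        seed = seed, prior = prior,
                        final_points = pts, add_final = add_final),
                   class = "ns")
  ie <- information_and_error(res)
  res$H <- ie[["H"]]
  res$logZ_error <- ie[["logZ_error"]]
  res
}

posterior_weights <- function(result) {
  w <- exp(result$samples$logWt - result$logZ)
  w / sum(w)
}

#' Posterior moments from a nested sampling run
#'
#' Each discarded point i carries weight p_i = L_i dX_i / Z; the weights
#' are renormalized to sum to one and used to form the posterior mean,
#' standard deviation and coefficient of variation (sd/mean) of every
#' parameter.  A small cv marks a tightly constrained (identifiable)
#' parameter.
#'
#' @param result an \code{"ns"} object.
#' @return Data frame with columns \code{parameter, mean, sd, cv}.
#' @export
posterior_moments <- function(result) {
  stopifnot(inherits(result, "ns"), is.finite(result$logZ))
  p <- posterior_weights(result)
  d <- result$prior$d
  th <- as.matrix(result$samples[, 2:(d + 1), drop = FALSE])
  mean_j <- colSums(p * th)
  var_j <- colSums(p * th^2) - mean_j^2
  neg <- var_j < 0
  if (any(neg)) {
    warning("negative posterior variance from rounding; clipped at 0")
    var_j[neg] <- 0
  }
  sd_j <- sqrt(var_j)
  data.frame(parameter = colnames(th), mean = mean_j, sd = sd_j,
             cv = sd_j / mean_j, row.names = NULL)
}

#' Information and evidence uncertainty
#'
#' H is the expected log-ratio of posterior to prior,
#' sum of p_i (logL_i - logZ); the dominant uncertainty in logZ comes from
#' the Beta(n, 1) shrinkage and scales as sqrt(H/n).
#'
#' @param result an \code{"ns"} object.
#' @return Named numeric vector \code{c(H, logZ_error)}.
#' @export
information_and_error <- function(result) {
  p <- posterior_weights(result)
  lp <- result$samples$logL - result$logZ
  H <- sum(ifelse(p > 0, p * lp, 0))
  if (!is.finite(H) || H < 0) H <- 0
  c(H = H, logZ_error = sqrt(H / result$n))
}

#' @export
print.ns <- function(x, ...) {
  cat(sprintf("Nested sampling: logZ = %.4f +/- %.4f  (H = %.2f, n = %d)\n",
              x$logZ, x$logZ_error, x$H, x$n))
  cat(sprintf("  %d posterior points, %d likelihood evaluations, stopped by %s\n",
              x$m, x$n_evals, x$termination))
  invisible(x)
}

#' @export
summary.ns <- function(object, ...) {
  mom <- posterior_moments(object)
  mom <- mom[order(mom$cv), ]
  rownames(mom) <- NULL
  structure(list(logZ = object$logZ, logZ_error = object$logZ_error,
                 H = object$H, n = object$n, m = object$m,
                 n_evals = object$n_evals, termination = object$termination,
                 moments = mom), class = "summary.ns")
}

#' @export
print.summary.ns <- function(x, ...) {
  cat(sprintf("log Z = %.4f +/- %.4f   H = %.3f   n = %d active points\n",
              x$logZ, x$logZ_error, x$H, x$n))
  cat(sprintf("%d posterior points; %d likelihood evaluations; stopped by %s\n",
              x$m, x$n_evals, x$termination))
  cat("Posterior moments (most to least constrained):\n")
  print(transform(x$moments, mean = signif(mean, 4), sd = signif(sd, 4),
                  cv = signif(cv, 4)))
  invisible(x)
}

#' @export
coef.ns <- function(object, ...) {
  mom <- posterior_moments(object)
  stats::setNames(mom$mean, mom$parameter)
}

#' @export
as.data.frame.ns <- function(x, ...) x$samples

#' @export
plot.ns <- function(x, which = c("weights", "posterior"), ...) {
  which <- match.arg(which)
  if (which == "weights") {
    graphics::plot(x$samples$iteration, x$samples$logWt, type = "l",
                   xlab = "iteration", ylab = "logWt",
                   main = "Posterior point weights", ...)
  } else {
    p <- posterior_weights(x)
    d <- x$prior$d
    op <- graphics::par(mfrow = c(ceiling(d / 3), min(d, 3)),
                        mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
    for (j in seq_len(d)) {
      th <- x$samples[[j + 1]]
      graphics::plot(th, p, pch = 16, cex = 0.4,
                     xlab = names(x$samples)[j + 1], ylab = "weight", ...)
    }
  }
  invisible(x)
}
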