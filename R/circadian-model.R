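#' Kinetic parameters of the single-loop circadian clock model
#'
#' Constructs and validates the parameter set of the three-species
#' Neurospora crassa clock model: FRQ mRNA (M), cytoplasmic protein (Pc)
#' and nuclear protein (Pn).  Transcription is repressed by nuclear
#' protein through a Hill term, mRNA and protein degradation follow
#' Michaelis-Menten kinetics, and translation and nuclear transport are
#' first order.  Defaults are the published free-running parameter set of
#' the source ODE model, which sustains oscillations with a period of
#' about 21.5 h in constant darkness.
#'
#' @param vs maximum transcription rate (conc/h).
#' @param kI Michaelis constant of transcriptional repression (conc).
#' @param vm maximum mRNA degradation rate (conc/h).
#' @param km Michaelis constant of mRNA degradation (conc).
#' @param ks translation rate (1/h).
#' @param vd maximum protein degradation rate (conc/h).
#' @param kd Michaelis constant of protein degradation (conc).
#' @param k1 cytoplasm-to-nucleus transport rate (1/h).
#' @param k2 nucleus-to-cytoplasm transport rate (1/h).
#' @param N Hill coefficient (positive integer); the binding cooperativity
#'   of repression and the index used for model selection.
#' @param omega system size (molecules per concentration unit); converts
#'   deterministic concentrations to stochastic counts.
#' @return An object of class \code{"circadian_parameters"} (named list).
#' @examples
#' p <- circadian_parameters()
#' p$vs
#' @export
circadian_parameters <- function(vs = 1.6, kI = 1, vm = 0.505, km = 0.5,
                                 ks = 0.5, vd = 1.4, kd = 0.13, k1 = 0.5,
                                 k2 = 0.6, N = 4, omega = 500) {
  p <- list(vs = vs, kI = kI, vm = vm, km = km, ks = ks, vd = vd, kd = kd,
            k1 = k1, k2 = k2, N = N, omega = omega)
  rates <- unlist(p[c("vs", "kI", "vm", "km", "ks", "vd", "kd", "k1", "k2")])
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("all kinetic constants must be strictly positive")
  if (N < 1 || N != round(N)) stop("Hill coefficient N must be an integer >= 1")
  if (!is.finite(omega) || omega <= 0) stop("system size omega must be > 0")
  structure(p, class = "circadian_parameters")
}

#' @export
print.circadian_parameters <- function(x, ...) {
  cat("Circadian clock parameters (single negative feedback loop):\n")
  v <- unlist(x)
  print(round(v, 4))
  invisible(x)
}

#' Names of the nine freely inferred kinetic constants
#'
#' The Hill coefficient N and the system size omega are held fixed in all
#' circadian inference runs; the remaining nine constants are integrated.
#'
#' @return Character vector of parameter names.
#' @export
free_parameter_names <- function() {
  c("vs", "kI", "vm", "km", "ks", "vd", "kd", "k1", "k2")
}

# Numeric vector layout shared with the compiled core.
par_vec <- function(params) {
  stopifnot(inherits(params, "circadian_parameters"))
  as.numeric(unlist(params[c("vs", "kI", "vm", "km", "ks", "vd", "kd",
                             "k1", "k2", "N", "omega")]))
}

#' Light forcing protocol
#'
#' Describes the environmental light input: constant darkness (DD,
#' free-running) or entraining light-dark cycles (LD) in which the
#' transcription rate is raised by \code{thetaM} between dawn and dusk.
#'
#' @param mode \code{"DD"} or \code{"LD"}.
#' @param thetaM forcing amplitude added to the transcription rate during
#'   the light phase (conc/h); default 0.8.
#' @param t_dawn,t_dusk lights-on / lights-off times (h in [0, 24)).
#' @return An object of class \code{"light_protocol"}.
#' @examples
#' light_protocol("LD", t_dawn = 0, t_dusk = 12)
#' @export
light_protocol <- function(mode = c("DD", "LD"), thetaM = 0.8, t_dawn = 0,
                           t_dusk = 12) {
  mode <- match.arg(mode)
  if (mode == "LD") {
    if (!(t_dawn >= 0 && t_dawn < 24 && t_dusk >= 0 && t_dusk < 24))
      stop("t_dawn and t_dusk must lie in [0, 24)")
    if (t_dawn >= t_dusk) stop("LD mode requires t_dawn < t_dusk")
    if (thetaM <= 0) stop("LD mode requires thetaM > 0")
  }
  structure(list(mode = mode, thetaM = thetaM, t_dawn = t_dawn,
                 t_dusk = t_dusk), class = "light_protocol")
}

#' @export
print.light_protocol <- function(x, ...) {
  if (x$mode == "DD") cat("Constant darkness (DD): theta(t) = 0\n")
  else cat(sprintf("Light-dark cycles: theta = %.3g for %g <= mod(t, 24) <= %g, else 0\n",
                   x$thetaM, x$t_dawn, x$t_dusk))
  invisible(x)
}

prot_vec <- function(protocol) {
  stopifnot(inherits(protocol, "light_protocol"))
  c(as.numeric(protocol$mode == "LD"), protocol$thetaM, protocol$t_dawn,
    protocol$t_dusk)
}

#' Light forcing term
#'
#' The time-dependent addition to the transcription rate.  Returns
#' \code{thetaM} when \code{mod(t, 24)} falls inside the light window of an
#' LD protocol and 0 otherwise; identically 0 in DD.
#'
#' @param t time in hours (vectorized).
#' @param protocol a \code{\link{light_protocol}}.
#' @return Numeric vector of forcing values (conc/h).
#' @examples
#' light_theta(30, light_protocol("LD", 0.8, 0, 12))  # mod(30, 24) = 6 -> 0.8
#' @export
light_theta <- function(t, protocol) {
  if (protocol$mode == "DD") return(rep(0, length(t)))
  tm <- t %% 24
  ifelse(tm >= protocol$t_dawn & tm <= protocol$t_dusk, protocol$thetaM, 0)
}

#' Deterministic right-hand side of the clock ODEs
#'
#' Time derivatives of (M, Pc, Pn) on the concentration scale:
#' Hill-repressed, light-boosted transcription and Michaelis-Menten
#' degradation for mRNA; translation, saturating degradation and linear
#' nuclear shuttling for the protein pools.
#'
#' @param state numeric vector \code{c(M, Pc, Pn)} (concentrations).
#' @param t time (h); only relevant under LD forcing.
#' @param params a \code{\link{circadian_parameters}} object.
#' @param protocol a \code{\link{light_protocol}}.
#' @return Numeric vector of the three derivatives (conc/h).
#' @export
ode_rhs <- function(state, t, params, protocol = light_protocol("DD")) {
  M <- state[1]; Pc <- state[2]; Pn <- state[3]
  th <- light_theta(t, protocol)
  kIN <- params$kI^params$N
  dM <- (params$vs + th) * kIN / (kIN + Pn^params$N) -
    params$vm * M / (params$km + M)
  dPc <- params$ks * M - params$vd * Pc / (params$kd + Pc) -
    params$k1 * Pc + params$k2 * Pn
  dPn <- params$k1 * Pc - params$k2 * Pn
  c(dM, dPc, dPn)
}

#' Integrate the clock ODEs
#'
#' Adaptive-step integration (lsoda) of the deterministic model.  Under LD
#' forcing the dawn/dusk discontinuities are honoured by integrating each
#' constant-light segment separately, so the integrator never steps across
#' a switch.
#'
#' @param params a \code{\link{circadian_parameters}} object.
#' @param protocol a \code{\link{light_protocol}}.
#' @param t_end end time (h).
#' @param output_step output grid spacing (h).
#' @param initial_state concentrations at t = 0; default (0.1, 0.1, 0.1),
#'   from which the limit cycle is reached after a transient.
#' @param rtol,atol integrator tolerances.
#' @return A data frame with columns \code{time_h, M, Pc, Pn}.
#' @examples
#' tr <- simulate_deterministic(circadian_parameters(), t_end = 48)
#' head(tr)
#' @export
simulate_deterministic <- function(params, protocol = light_protocol("DD"),
                                   t_end, output_step = 0.1,
                                   initial_state = c(0.1, 0.1, 0.1),
                                   rtol = 1e-8, atol = 1e-10) {
  stopifnot(t_end > 0, output_step > 0)
  func <- function(t, y, parms) list(ode_rhs(y, t, params, protocol))
  grid <- seq(0, t_end, by = output_step)
  if (abs(grid[length(grid)] - t_end) > 1e-9) grid <- c(grid, t_end)
  if (protocol$mode == "LD") {
    sw <- sort(unique(c(outer(c(protocol$t_dawn, protocol$t_dusk),
                              24 * (0:ceiling(t_end / 24)), "+"))))
    sw <- sw[sw > 0 & sw < t_end]
  } else sw <- numeric(0)
  bounds <- c(0, sw, t_end)
  y <- initial_state
  rows <- list(matrix(c(0, initial_state), nrow = 1))
  for (k in seq_len(length(bounds) - 1)) {
    a <- bounds[k]; b <- bounds[k + 1]
    seg_out <- grid[grid > a + 1e-12 & grid <= b + 1e-12]
    tt <- unique(c(a, seg_out, b))
    sol <- deSolve::ode(y = y, times = tt, func = func, parms = NULL,
                        rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("ODE integration failed near t = %.3f h", a))
    y <- as.numeric(sol[nrow(sol), 2:4])
    keep <- sol[, 1] %in% seg_out
    if (any(keep)) rows[[length(rows) + 1]] <- unclass(sol)[keep, , drop = FALSE]
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("time_h", "M", "Pc", "Pn")
  rownames(out) <- NULL
  out[c("M", "Pc", "Pn")] <- lapply(out[c("M", "Pc", "Pn")], pmax, 0)
  out
}

#' Estimate the oscillation period from a trajectory
#'
#' Mean peak-to-peak interval of one species after discarding an initial
#' transient.  Peaks are interior local maxima found by three-point
#' comparison on the output grid; ties broken by first occurrence.
#'
#' @param trajectory a data frame as returned by
#'   \code{\link{simulate_deterministic}} (columns \code{time_h} and the
#'   species).
#' @param species which species to use; default \code{"M"}.
#' @param transient initial span to discard (h); default 48.
#' @return Estimated period in hours, or \code{NA_real_} if fewer than two
#'   interior maxima remain (non-oscillatory input).
#' @examples
#' tr <- simulate_deterministic(circadian_parameters(), t_end = 240)
#' estimate_period(tr)  # about 21.5
#' @export
estimate_period <- function(trajectory, species = "M", transient = 48) {
  keep <- trajectory$time_h > transient
  x <- trajectory[[species]][keep]
  tt <- trajectory$time_h[keep]
  if (length(x) < 3) return(NA_real_)
  i <- which(x[2:(length(x) - 1)] > x[1:(length(x) - 2)] &
               x[2:(length(x) - 1)] > x[3:length(x)]) + 1
  if (length(i) < 2) return(NA_real_)
  mean(diff(tt[i]))
}

#' Per-species birth and death rates on the count scale
#'
#' The aggregated birth and death rates of each molecular species, derived
#' from the six reaction propensities: saturating (Hill/Michaelis) terms
#' take concentrations (count/omega), first-order rates act directly on
#' counts, and the zero-order transcription term is multiplied by omega.
#' Transport contributes a birth to one protein pool and a death to the
#' other.  These rates define the transitional likelihood moments
#' mu = (beta - delta) * dT and sigma^2 = (beta + delta) * dT.
#'
#' @param state numeric vector \code{c(M, Pc, Pn)} of molecule counts.
#' @param t time (h).
#' @param params a \code{\link{circadian_parameters}} object.
#' @param protocol a \code{\link{light_protocol}}.
#' @return A 3 x 2 matrix with rows \code{M, Pc, Pn} and columns
#'   \code{beta, delta} (molecules/h).
#' @examples
#' p <- circadian_parameters()
#' birth_death_rates(c(500, 300, 200), 0, p)
#' @export
birth_death_rates <- function(state, t, params,
                              protocol = light_protocol("DD")) {
  stopifnot(length(state) == 3, all(state >= 0))
  out <- cpp_bd_rates(as.numeric(state), t, par_vec(params),
                      prot_vec(protocol))
  dimnames(out) <- list(c("M", "Pc", "Pn"), c("beta", "delta"))
  out
}
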