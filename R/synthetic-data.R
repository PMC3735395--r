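#' Exact stochastic simulation of the clock model
#'
#' Gillespie direct-method realisation of the six elementary reactions
#' (Hill-repressed transcription, Michaelis-Menten mRNA and protein
#' degradation, translation, and nuclear import/export) on the count scale
#' at system size omega.  Light-dark forcing is handled exactly by
#' simulating each constant-light segment separately.  The state is
#' recorded on a fixed fine grid.
#'
#' @param params a \code{\link{circadian_parameters}} object.
#' @param protocol a \code{\link{light_protocol}}.
#' @param t_end end time (h).
#' @param seed integer seed; identical seeds give identical trajectories.
#' @param record_dt recording grid spacing (h); default 0.1.
#' @param initial_counts integer counts \code{c(M, Pc, Pn)} at t = 0; by
#'   default \code{round(omega * x)} where x is the deterministic DD state
#'   after a 240 h burn-in, so realisations start on the limit cycle.
#' @param max_events safety cap on the number of reaction events.
#' @return A \code{"clock_ts"} object: data frame \code{time_h, M, Pc, Pn}
#'   with protocol/seed metadata attributes.
#' @examples
#' ts <- ssa_simulate(circadian_parameters(), t_end = 24, seed = 1)
#' head(ts)
#' @export
ssa_simulate <- function(params, protocol = light_protocol("DD"), t_end,
                         seed = NULL, record_dt = 0.1, initial_counts = NULL,
                         max_events = 5e8) {
  stopifnot(t_end > 0, record_dt > 0)
  if (is.null(initial_counts))
    initial_counts <- default_initial_counts(params)
  stopifnot(length(initial_counts) == 3, all(initial_counts >= 0),
            all(initial_counts == round(initial_counts)))
  if (!is.null(seed)) set.seed(seed)
  m <- cpp_ssa(as.numeric(initial_counts), t_end, par_vec(params),
               prot_vec(protocol), record_dt, max_events)
  out <- as.data.frame(m)
  names(out) <- c("time_h", "M", "Pc", "Pn")
  new_clock_ts(out, sampling_interval = record_dt, protocol = protocol,
               omega = params$omega, seed = seed, params = params)
}

#' Default stochastic initial state on the limit cycle
#'
#' \code{round(omega * x(240))} where x is the deterministic DD trajectory
#' from the standard initial concentrations; cached per parameter set
#' within a session.
#'
#' @param params a \code{\link{circadian_parameters}} object.
#' @return Integer vector \code{c(M, Pc, Pn)} of counts.
#' @export
default_initial_counts <- function(params) {
  key <- paste(signif(unlist(params), 12), collapse = ",")
  hit <- .clockns_cache$init[[key]]
  if (!is.null(hit)) return(hit)
  tr <- simulate_deterministic(params, light_protocol("DD"), t_end = 240,
                               output_step = 1)
  x <- as.numeric(tr[nrow(tr), c("M", "Pc", "Pn")])
  counts <- round(params$omega * x)
  .clockns_cache$init[[key]] <- counts
  counts
}

.clockns_cache <- new.env(parent = emptyenv())
.clockns_cache$init <- list()

new_clock_ts <- function(df, sampling_interval, protocol, omega, seed,
                         params = NULL, cycles = NA_integer_,
                         replicate_id = NA_integer_) {
  structure(df, class = c("clock_ts", "data.frame"),
            sampling_interval = sampling_interval, protocol = protocol,
            omega = omega, seed = seed, params = params, cycles = cycles,
            replicate_id = replicate_id)
}

#' @export
as.data.frame.clock_ts <- function(x, ...) {
  keep <- c("names", "row.names")
  for (a in setdiff(names(attributes(x)), keep)) attr(x, a) <- NULL
  class(x) <- "data.frame"
  x
}

#' @export
print.clock_ts <- function(x, ...) {
  p <- attr(x, "protocol")
  cat(sprintf("Clock time series: %d points, interval %g h, %s, omega = %g\n",
              nrow(x), attr(x, "sampling_interval"),
              if (is.null(p)) "?" else p$mode, attr(x, "omega")))
  print.data.frame(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Sparsely sample a finely recorded time series
#'
#' Retains the states at times 0, interval, 2*interval, ...; emulates the
#' sparse experimental protocol of sampling molecule counts every 2 h.
#'
#' @param fine a \code{"clock_ts"} on a fine grid.
#' @param interval sampling interval (h); must be a positive multiple of
#'   the fine recording resolution.
#' @return A \code{"clock_ts"} with updated metadata.
#' @examples
#' fine <- ssa_simulate(circadian_parameters(), t_end = 24, seed = 1)
#' nrow(sparse_sample(fine, 2))  # 13
#' @export
sparse_sample <- function(fine, interval) {
  res <- attr(fine, "sampling_interval")
  k <- interval / res
  if (interval <= 0 || abs(k - round(k)) > 1e-9)
    stop("interval must be a positive multiple of the fine resolution")
  keep <- which(abs(fine$time_h %% interval) < res / 2 |
                  abs(fine$time_h %% interval - interval) < res / 2)
  out <- as.data.frame(fine)[keep, , drop = FALSE]
  rownames(out) <- NULL
  new_clock_ts(out, sampling_interval = interval,
               protocol = attr(fine, "protocol"), omega = attr(fine, "omega"),
               seed = attr(fine, "seed"), params = attr(fine, "params"),
               cycles = attr(fine, "cycles"),
               replicate_id = attr(fine, "replicate_id"))
}

#' Derive a replicate seed from a base seed
#'
#' Stable linear congruential mix of (condition, cycles, replicate) into a
#' base seed, modulo the Mersenne prime 2^31 - 1, so distinct design
#' triples receive distinct reproducible seeds.
#'
#' @param base_seed integer base seed.
#' @param condition condition label (e.g. \code{"DD"}, \code{"LD"}).
#' @param cycles number of 24 h cycles.
#' @param replicate replicate index.
#' @return Integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(base_seed, condition, cycles, replicate) {
  m <- 2147483647
  h <- (as.numeric(base_seed) %% m)
  for (k in c(utf8ToInt(as.character(condition)), 1000003 + cycles,
              2000003 + replicate)) {
    h <- (h * 48271 + k) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

#' Generate the synthetic experimental dataset
#'
#' Independent stochastic realisations of the clock model for each
#' combination of condition, time span and replicate, sparsely sampled.
#' The default design is 1-5 cycles of 24 h, five replicates, sampled
#' every 2 h, in DD and/or LD conditions.
#'
#' @param params generating \code{\link{circadian_parameters}}.
#' @param conditions named list of \code{\link{light_protocol}} objects;
#'   default \code{list(DD = light_protocol("DD"))}.
#' @param cycles_list numbers of 24 h cycles to span; default 1:5.
#' @param replicates replicates per (condition, cycles) cell; default 5.
#' @param base_seed base integer seed.
#' @param interval sparse sampling interval (h); default 2.
#' @param record_dt fine recording grid for the underlying SSA (h).
#' @return A list of \code{"clock_ts"} objects named
#'   \code{"<condition>_c<cycles>_r<replicate>"}.
#' @examples
#' ds <- generate_dataset(circadian_parameters(), cycles_list = 1,
#'                        replicates = 2, base_seed = 7)
#' names(ds)
#' @export
generate_dataset <- function(params,
                             conditions = list(DD = light_protocol("DD")),
                             cycles_list = 1:5, replicates = 5,
                             base_seed = 1, interval = 2, record_dt = 0.1) {
  stopifnot(replicates >= 1)
  out <- list()
  for (cond in names(conditions)) {
    for (cyc in cycles_list) {
      for (rep_i in seq_len(replicates)) {
        seed <- derive_seed(base_seed, cond, cyc, rep_i)
        fine <- ssa_simulate(params, conditions[[cond]], t_end = cyc * 24,
                             seed = seed, record_dt = record_dt)
        ts <- sparse_sample(fine, interval)
        attr(ts, "cycles") <- cyc
        attr(ts, "replicate_id") <- rep_i
        out[[sprintf("%s_c%d_r%d", cond, cyc, rep_i)]] <- ts
      }
    }
  }
  out
}

#' Write a clock time series as CSV plus JSON sidecar
#'
#' The CSV has header \code{time_h,M,Pc,Pn}; the sidecar
#' (\code{<path>.json}) records seed, protocol, system size, sampling
#' interval and the generating parameters.
#'
#' @param ts a \code{"clock_ts"}.
#' @param path CSV output path.
#' @return \code{path}, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  utils::write.csv(as.data.frame(ts)[c("time_h", "M", "Pc", "Pn")], path,
                   row.names = FALSE, quote = FALSE)
  p <- attr(ts, "protocol")
  meta <- list(seed = attr(ts, "seed"), omega = attr(ts, "omega"),
               sampling_interval = attr(ts, "sampling_interval"),
               cycles = attr(ts, "cycles"),
               replicate_id = attr(ts, "replicate_id"),
               protocol = if (!is.null(p)) unclass(p),
               params = if (!is.null(attr(ts, "params")))
                 unclass(attr(ts, "params")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a clock time series written by \code{\link{write_timeseries}}
#'
#' @param path CSV path; the JSON sidecar \code{<path>.json} is read if
#'   present.
#' @return A \code{"clock_ts"} object.
#' @export
read_timeseries <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_h", "M", "Pc", "Pn") %in% names(df)))
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
  else list()
  prot <- NULL
  if (!is.null(meta$protocol))
    prot <- light_protocol(meta$protocol$mode, meta$protocol$thetaM,
                           meta$protocol$t_dawn, meta$protocol$t_dusk)
  params <- NULL
  if (!is.null(meta$params)) params <- do.call(circadian_parameters, meta$params)
  interval <- meta$sampling_interval
  if (is.null(interval))
    interval <- if (nrow(df) > 1) df$time_h[2] - df$time_h[1] else NA_real_
  new_clock_ts(df[c("time_h", "M", "Pc", "Pn")],
               sampling_interval = interval, protocol = prot,
               omega = if (is.null(meta$omega)) NA_real_ else meta$omega,
               seed = meta$seed, params = params,
               cycles = if (is.null(meta$cycles)) NA_integer_ else meta$cycles,
               replicate_id = if (is.null(meta$replicate_id)) NA_integer_
               else meta$replicate_id)
}
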