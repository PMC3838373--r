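# trace column layout; must match the sampling order of the compiled loop
.trace_cols <- function() {
  pool <- c(paste0("fast_", MUSCLES), paste0("slow_", MUSCLES))
  c("t", "alpha", "beta", "gamma", "alpha_dot", "beta_dot", "gamma_dot",
    paste0("V_C", 1:6),
    paste0("A_", pool),
    paste0("k_res_slow_", MUSCLES),
    paste0("k_total_", pool),
    paste0("force_", pool),
    paste0("spikes_", pool),
    "phase_PR", "phase_LD", "phase_EF",
    "gate_fast_PR", "gate_fast_EF", "gate_slow_PR", "gate_slow_EF",
    "gate_LD", "latch", "in_contact", "ci_active", "stop_active",
    "start_active",
    paste0("g_drive_C", 1:6))
}

.event_labels <- c(
  "stop_command", "start_command", "fast_PR_switch", "fast_EF_switch",
  "slow_PR_enhanced", "slow_EF_enhanced", "ground_contact_latch",
  "slow_PR_off", "slow_EF_off", "PR_enabled", "EF_enabled", "LD_enabled",
  "beta_cross_PR_up", "beta_cross_PR_down", "beta_cross_EF_up",
  "beta_cross_EF_down", "start_mode_selected")

#' Run the coupled leg simulation
#'
#' Integrates the full neuro-mechanical system - three CPG half-centres,
#' twelve motoneuron pools, twelve muscles and three joints - with a single
#' fixed-step RK4 loop.  Discrete events (sensory threshold crossings,
#' command onsets, gate switches, the ground-contact latch, start-cascade
#' releases) are processed at step boundaries in a fixed order: sensors,
#' rules, neurons, muscles, mechanics.  The run is fully deterministic:
#' identical configurations yield identical traces.
#'
#' @param cfg A [leg_config()].
#' @return An object of class `"leg_sim"`: a list with
#'   \describe{
#'     \item{trace}{data frame, one row per sample (every
#'       `stride * dt` ms): joint angles and velocities, CPG membrane
#'       potentials, per-pool activations, residual/total stiffness,
#'       forces and spike counts, phase flags, gate levels, latch/contact
#'       flags, command flags, and the (constant) CPG drive conductances.}
#'     \item{events}{data frame `time`, `event`, `value` of all discrete
#'       events.}
#'     \item{spikes}{list of spike-time vectors, one per motoneuron pool.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
#' @examples
#' sim <- leg_simulate(leg_config(sim = list(duration = 2000)))
#' summary(sim)
leg_simulate <- function(cfg = leg_config()) {
  cfg <- validate_config(cfg)
  pars <- .flatten_params(cfg)
  sched <- .flatten_schedule(cfg)
  out <- cpp_simulate(pars, sched, unname(cfg$init$angles),
                      .cpg_init_state(), cfg$sim$dt, cfg$sim$duration,
                      as.integer(cfg$sim$stride),
                      isTRUE(cfg$init$start_at_rest))
  trace <- as.data.frame(out$trace)
  names(trace) <- .trace_cols()
  ev <- as.data.frame(out$events)
  if (nrow(ev)) {
    names(ev) <- c("time", "code", "value")
    ev$event <- .event_labels[ev$code]
    ev <- ev[c("time", "event", "value")]
  } else {
    ev <- data.frame(time = numeric(0), event = character(0),
                     value = numeric(0))
  }
  spikes <- out$spikes
  names(spikes) <- c(paste0("fast_", MUSCLES), paste0("slow_", MUSCLES))
  structure(list(trace = trace, events = ev, spikes = spikes, config = cfg),
            class = "leg_sim")
}

#' @export
print.leg_sim <- function(x, ...) {
  tr <- x$trace
  cat(sprintf("<leg_sim> %g ms, %d samples, %d events\n",
              max(tr$t), nrow(tr), nrow(x$events)))
  fin <- tr[nrow(tr), ]
  cat(sprintf("  final angles: alpha %.2f, beta %.2f, gamma %.2f deg\n",
              fin$alpha, fin$beta, fin$gamma))
  invisible(x)
}

#' @export
summary.leg_sim <- function(object, ...) {
  tr <- object$trace
  fin <- tr[nrow(tr), ]
  stepping <- tr[tr$stop_active == 0 & tr$latch == 0, ]
  per <- tryCatch(cpg_period(tr), error = function(e) NA_real_)
  out <- list(
    duration = max(tr$t),
    cpg_period = per,
    stepping_range = if (nrow(stepping) > 10)
      sapply(stepping[c("alpha", "beta", "gamma")], range) else NULL,
    final = unlist(fin[c("alpha", "beta", "gamma")]),
    final_still = max(abs(unlist(fin[c("alpha_dot", "beta_dot", "gamma_dot")]))),
    latched = fin$latch == 1,
    n_events = nrow(object$events)
  )
  class(out) <- "summary.leg_sim"
  out
}

#' @export
print.summary.leg_sim <- function(x, ...) {
  cat(sprintf("leg simulation, %g ms (free-running CPG period %.1f ms)\n",
              x$duration, x$cpg_period))
  if (!is.null(x$stepping_range)) {
    r <- x$stepping_range
    cat(sprintf("  stepping excursions: alpha [%.1f, %.1f], beta [%.1f, %.1f], gamma [%.1f, %.1f] deg\n",
                r[1, 1], r[2, 1], r[1, 2], r[2, 2], r[1, 3], r[2, 3]))
  }
  cat(sprintf("  final posture: alpha %.3f, beta %.3f, gamma %.3f deg (max |vel| %.2e)%s\n",
              x$final[1], x$final[2], x$final[3], x$final_still,
              if (x$latched) ", ground contact latched" else ""))
  invisible(x)
}

#' @export
plot.leg_sim <- function(x, which = c("angles", "cpg", "activity"), ...) {
  which <- match.arg(which)
  tr <- x$trace
  if (which == "angles") {
    matplot(tr$t, tr[c("alpha", "beta", "gamma")], type = "l", lty = 1,
            col = c("red", "black", "darkgreen"),
            xlab = "time (ms)", ylab = "joint angle (deg)", ...)
    legend("topright", legend = c(expression(alpha), expression(beta),
                                  expression(gamma)),
           col = c("red", "black", "darkgreen"), lty = 1, bty = "n")
  } else if (which == "cpg") {
    matplot(tr$t, tr[paste0("V_C", 1:6)], type = "l", lty = 1,
            xlab = "time (ms)", ylab = "V (mV)", ...)
  } else {
    matplot(tr$t, tr[c("A_fast_protractor", "A_slow_protractor")],
            type = "l", lty = 1, col = c("blue", "red"),
            xlab = "time (ms)", ylab = "activation", ...)
    legend("topright", legend = c("fast protractor", "slow protractor"),
           col = c("blue", "red"), lty = 1, bty = "n")
  }
  invisible(x)
}

#' @importFrom graphics matplot legend
NULL

#' Free-running CPG period of a trace
#'
#' Mean interval between successive upward crossings of the
#' phase-classification threshold by C1 during stepping.
#'
#' @param trace A `leg_sim` trace (or the data frame).
#' @param V_thr Classification threshold (mV).
#' @return Period (ms).
#' @export
cpg_period <- function(trace, V_thr = leg_config()$cpg$V_thr) {
  if (inherits(trace, "leg_sim")) trace <- trace$trace
  # measure on the stepping portion where the systems are entrained
  if (!is.null(trace$stop_active) && any(trace$stop_active == 0))
    trace <- trace[trace$stop_active == 0 & trace$latch == 0, ]
  up <- which(diff(trace$V_C1 > V_thr) == 1)
  if (length(up) < 3) return(NA_real_)
  per <- diff(trace$t[up])
  # guard against a gap between stepping epochs
  mean(per[per < 2 * stats::median(per)])
}

#' Extract swing/stance phase intervals from a trace
#'
#' Partitions the stepping portion of a trace into labelled intervals.
#' The swing phase is defined by the levation angle being above the stance
#' band; within each system, sub-phases follow the sign of the joint's
#' angular velocity (retraction while alpha increases, and so on).
#'
#' @param x A `leg_sim` object or trace data frame.
#' @param system `"leg"` (swing/stance from beta), `"PR"`, `"LD"` or
#'   `"EF"` (movement phases from the respective velocity sign).
#' @param min_duration Minimum interval length (ms); shorter intervals
#'   (velocity jitter around zero) are merged with their successor.
#' @param vel_eps Velocity dead band (deg/ms): |velocity| below this is
#'   "still".
#' @return A data frame with `start`, `end`, `phase`.  A trace with no
#'   movement yields zero rows.
#' @export
extract_phases <- function(x, system = c("leg", "PR", "LD", "EF"),
                           min_duration = 40, vel_eps = 0.02) {
  system <- match.arg(system)
  tr <- if (inherits(x, "leg_sim")) x$trace else x
  if (system == "leg") {
    cfg_gc <- if (inherits(x, "leg_sim")) x$config$rules$beta_gc else 34
    lab <- ifelse(tr$beta > cfg_gc + 2, "swing", "stance")
  } else {
    vel <- switch(system, PR = tr$alpha_dot, LD = tr$beta_dot,
                  EF = tr$gamma_dot)
    up <- switch(system, PR = "retraction", LD = "levation", EF = "flexion")
    dn <- switch(system, PR = "protraction", LD = "depression",
                 EF = "extension")
    lab <- ifelse(vel > vel_eps, up, ifelse(vel < -vel_eps, dn, "still"))
  }
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  out <- data.frame(start = tr$t[starts], end = tr$t[ends], phase = r$values,
                    stringsAsFactors = FALSE)
  out <- out[out$end - out$start >= min_duration, , drop = FALSE]
  if (nrow(out) && all(out$phase == "still"))
    out <- out[0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Time of convergence of a series to a target
#'
#' First time after which the series stays within the tolerance band of
#' the target for the remainder of the trace.
#'
#' @param time Sample times (ms).
#' @param series Values.
#' @param target Target value.
#' @param tolerance Half-width of the band.
#' @return The convergence time (ms), or `NA` (with a message) if the
#'   series leaves the band up to and including its final sample.
#' @export
convergence_time <- function(time, series, target, tolerance) {
  outside <- abs(series - target) > tolerance
  if (outside[length(outside)]) {
    message("series has not converged within the trace")
    return(NA_real_)
  }
  if (!any(outside)) return(time[1])
  time[max(which(outside)) + 1]
}

#' Export a trace as delimited text
#'
#' One header line, one row per sample, comma-separated.
#'
#' @param x A `leg_sim` object.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_trace <- function(x, path) {
  write.csv(x$trace, path, row.names = FALSE)
  invisible(path)
}

#' Compact JSON summary of a run
#'
#' End state, event table and per-system phase table, as a JSON string or
#' file.
#'
#' @param x A `leg_sim` object.
#' @param path Optional output file.
#' @return The JSON string (invisibly if written to a file).
#' @export
summary_json <- function(x, path = NULL) {
  tr <- x$trace
  fin <- tr[nrow(tr), ]
  obj <- list(
    duration = max(tr$t),
    final = list(alpha = fin$alpha, beta = fin$beta, gamma = fin$gamma,
                 latched = fin$latch == 1),
    cpg_period = cpg_period(tr),
    events = x$events,
    phases = extract_phases(x, "leg")
  )
  json <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA)
  if (!is.null(path)) {
    jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
    return(invisible(json))
  }
  json
}
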