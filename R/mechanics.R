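#' Advance a joint state one step
#'
#' Second-order damped dynamics `I * theta'' = tau_net - b * theta'`,
#' integrated with one RK4 step.  If the joint is the levation joint and
#' the permanent ground-contact latch is set, the angle is held at the
#' ground-contact value with zero velocity (kinematic constraint).  Angles
#' are clamped to the configured anatomical range.
#'
#' @param state List with `angle` (deg), `angular_velocity` (deg/ms) and
#'   `joint_id` (`"ThC"`, `"CTr"` or `"FTi"`).
#' @param net_torque Net muscle torque (mN mm); may be a function of the
#'   angle (for position-dependent spring torques) or a constant.
#' @param inertia,damping Joint inertia and damping.
#' @param dt Step (ms) in `(0, 1]`.
#' @param contact Optional contact state (see [contact_update()]); only
#'   consulted for the `"CTr"` joint.
#' @param beta_gc Ground-contact levation angle (deg).
#' @param range Anatomical range `c(min, max)` (deg).
#' @return The updated state.
#' @export
joint_step <- function(state, net_torque, inertia, damping, dt,
                       contact = NULL, beta_gc = NULL,
                       range = c(-Inf, Inf)) {
  if (!is.numeric(dt) || dt <= 0 || dt > 1)
    stop("dt must be in (0, 1] ms", call. = FALSE)
  tau <- if (is.function(net_torque)) net_torque else function(th) net_torque
  if (!is.finite(tau(state$angle)))
    stop("non-finite torque on joint ", state$joint_id, call. = FALSE)
  if (identical(state$joint_id, "CTr") && isTRUE(contact$permanent_latch)) {
    state$angle <- beta_gc
    state$angular_velocity <- 0
    return(state)
  }
  th <- state$angle; om <- state$angular_velocity
  f <- function(th, om) c(om, (tau(th) - damping * om) / inertia)
  k1 <- f(th, om)
  k2 <- f(th + dt / 2 * k1[1], om + dt / 2 * k1[2])
  k3 <- f(th + dt / 2 * k2[1], om + dt / 2 * k2[2])
  k4 <- f(th + dt * k3[1], om + dt * k3[2])
  th <- th + dt / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
  om <- om + dt / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
  if (th < range[1]) { th <- range[1]; om <- max(om, 0) }
  if (th > range[2]) { th <- range[2]; om <- min(om, 0) }
  state$angle <- th
  state$angular_velocity <- om
  state
}

#' Detect levation-angle threshold crossings
#'
#' Scans a sampled levation-angle trace for debounced crossings of the two
#' critical angles that initiate phase transitions: `beta_crit_PR` for the
#' protractor-retractor system and `beta_crit_EF` for the extensor-flexor
#' system.  A crossing is only registered once the trace has moved a
#' hysteresis margin beyond the threshold, so sub-tolerance jitter produces
#' no events.  Because the two critical angles differ, a rising sweep
#' yields the PR event before the EF event (extension starts later than
#' protraction).
#'
#' @param time Sample times (ms).
#' @param beta Levation angle samples (deg).
#' @param thresholds List with `beta_crit_PR`, `beta_crit_EF`,
#'   `hysteresis` (defaults from [leg_config()]).
#' @return A data frame with columns `time`, `system` (`"PR"`/`"EF"`) and
#'   `direction` (`"up"` = into swing, `"down"` = into stance).
#' @export
beta_sensory_events <- function(time, beta, thresholds = leg_config()$rules) {
  stopifnot(length(time) == length(beta), !is.unsorted(time))
  scan <- function(thr, system) {
    h <- thresholds$hysteresis
    pos <- beta[1] > thr
    out <- NULL
    for (i in seq_along(beta)) {
      if (!pos && beta[i] > thr + h) {
        pos <- TRUE
        out <- rbind(out, data.frame(time = time[i], system = system,
                                     direction = "up"))
      } else if (pos && beta[i] < thr - h) {
        pos <- FALSE
        out <- rbind(out, data.frame(time = time[i], system = system,
                                     direction = "down"))
      }
    }
    out
  }
  ev <- rbind(scan(thresholds$beta_crit_PR, "PR"),
              scan(thresholds$beta_crit_EF, "EF"))
  if (is.null(ev))
    return(data.frame(time = numeric(0), system = character(0),
                      direction = character(0)))
  ev[order(ev$time), , drop = FALSE]
}

#' Update the ground-contact state
#'
#' The permanent ground-contact latch is set if and only if a stop episode
#' is active, the fast protractor-retractor and extensor-flexor gates have
#' already closed, the levation angle is within `eps_beta` of the
#' ground-contact angle and not rising (the depressor establishes the
#' contact at the end of the swing phase).  Once set, the latch persists
#' until the start command's cascade re-enables the levator-depressor
#' pools, and the levation angle is held exactly at the contact value.
#'
#' @param beta Levation angle (deg).
#' @param beta_dot Levation angular velocity (deg/ms).
#' @param thresholds List with `beta_gc` and `eps_beta`.
#' @param stop_gates_closed Logical: both fast gates closed?
#' @param stop_active Logical: stop episode active?
#' @param contact List with logical fields `in_contact`,
#'   `permanent_latch` and the value `beta_gc`.
#' @return The updated contact state.
#' @export
contact_update <- function(beta, beta_dot, thresholds, stop_gates_closed,
                           stop_active,
                           contact = list(in_contact = FALSE,
                                          permanent_latch = FALSE)) {
  contact$beta_gc <- thresholds$beta_gc
  if (!contact$permanent_latch && isTRUE(stop_active) &&
      isTRUE(stop_gates_closed) && beta_dot <= 0 &&
      abs(beta - thresholds$beta_gc) <= thresholds$eps_beta) {
    contact$permanent_latch <- TRUE
  }
  contact$in_contact <- contact$permanent_latch ||
    beta <= thresholds$beta_gc + thresholds$eps_beta
  contact
}
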