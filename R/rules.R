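# Pure-functional forms of the stop/start coordination rules.  The engine
# applies the same logic step-by-step in compiled code; these functions
# state the rule semantics on explicit gate states and are the reference
# for the rule-level unit tests.  All command action is on motoneuron-level
# gates; no rule ever touches a CPG drive conductance.

#' Fast-gate stop switch
#'
#' The once-only switch of a fast motoneuron gate: while the stop command
#' is on and the relevant angle (alpha for the PR system, gamma for the EF
#' system) is in its decreasing phase, the gate arms; the pools fall silent
#' when the ongoing swing-phase burst completes.  The switch occurs at most
#' once per stop epoch, so the leg never stops into a protraction in the
#' stance phase.
#'
#' @param gate List with `level` (`"normal"`, `"armed"` or `"reduced"`) and
#'   `once_latch` (logical).
#' @param stop_active Logical.
#' @param angular_velocity The relevant angular velocity (deg/ms).
#' @return The updated gate.
#' @export
stop_fast_gate <- function(gate, stop_active, angular_velocity) {
  stopifnot(is.finite(angular_velocity))
  if (isTRUE(stop_active) && !isTRUE(gate$once_latch) &&
      angular_velocity < 0) {
    gate$level <- "armed"
    gate$once_latch <- TRUE
  }
  gate
}

#' Fast-gate phase completion
#'
#' An armed fast gate becomes reduced (its pools silent) at the transition
#' of its system from the swing-like to the stance-like CPG phase, i.e.
#' at the end of the last protraction or extension.
#'
#' @param gate A fast gate (see [stop_fast_gate()]).
#' @param phase,prev_phase Current and previous phase of the system's CPG
#'   (`"swing"`/`"stance"`).
#' @return The updated gate.
#' @export
fast_gate_complete <- function(gate, phase, prev_phase) {
  if (identical(gate$level, "armed") && phase == "stance" &&
      prev_phase == "swing")
    gate$level <- "reduced"
  gate
}

#' Slow-pool enhancement at the stop command
#'
#' At stop onset the central inhibitory conductance onto the interneurons
#' of the slow PR and EF pools is enhanced, silencing the relays and
#' disinhibiting the pools into tonic firing (stronger than their
#' stepping-phase mean rate).  Re-issuing the command within the same epoch
#' is idempotent; the start command resets the enhancement.
#'
#' @param gate List with `level` (`"normal"`, `"enhanced"` or `"off"`).
#' @param stop_active Logical.
#' @return The updated gate.
#' @export
stop_slow_boost <- function(gate, stop_active) {
  if (isTRUE(stop_active) && identical(gate$level, "normal"))
    gate$level <- "enhanced"
  gate
}

#' Levator-depressor block at ground contact
#'
#' Both fast and slow levator and depressor pools are inhibited if and
#' only if the fast PR and EF gates have closed and the levation angle has
#' reached the ground-contact value (within tolerance, not rising); the
#' permanent ground-contact latch is set at the same moment.
#'
#' @param fast_gates_closed Logical: both fast gates reduced?
#' @param beta,beta_dot Levation angle (deg) and velocity (deg/ms).
#' @param thresholds List with `beta_gc`, `eps_beta`.
#' @param stop_active Logical.
#' @return Logical: should the levator-depressor pools be switched off (and
#'   the contact latched)?
#' @export
stop_levdep_gate <- function(fast_gates_closed, beta, beta_dot, thresholds,
                             stop_active) {
  isTRUE(stop_active) && isTRUE(fast_gates_closed) && beta_dot <= 0 &&
    abs(beta - thresholds$beta_gc) <= thresholds$eps_beta
}

#' Slow-pool switch-off near the stationary posture
#'
#' The tonically enhanced slow pools are switched off only once the
#' permanent ground contact is established, the controlled angle is within
#' `eps_angle` of its stationary value and the angular velocity is within
#' `eps_velocity` of zero.  The switch latches: a later transient
#' re-entry into the tolerance band does not re-arm the pool.
#'
#' @param gate A slow gate (see [stop_slow_boost()]).
#' @param angle,angular_velocity Controlled angle (deg) and velocity
#'   (deg/ms).
#' @param target Stationary target angle (deg).
#' @param latched Logical: permanent ground contact established?
#' @param eps_angle,eps_velocity Tolerances.
#' @return The updated gate.
#' @export
stop_slow_gate <- function(gate, angle, angular_velocity, target, latched,
                           eps_angle, eps_velocity) {
  if (identical(gate$level, "enhanced") && isTRUE(latched) &&
      abs(angle - target) <= eps_angle &&
      abs(angular_velocity) <= eps_velocity)
    gate$level <- "off"
  gate
}

#' Select the start mode
#'
#' Whether stepping restarts with a swing or a stance phase depends on the
#' stationary retraction angle relative to a critical angle: below the
#' critical angle the leg lifts off first (swing-first), at or above it
#' the leg first retracts and flexes on the ground (stance-first).
#'
#' @param alpha_s Stationary retraction angle (deg).
#' @param alpha_crit Critical angle (deg).
#' @return `"swing-first"` or `"stance-first"`.
#' @export
select_start_mode <- function(alpha_s, alpha_crit = leg_config()$rules$alpha_crit) {
  if (alpha_s < alpha_crit) "swing-first" else "stance-first"
}

#' Common-inhibitor state
#'
#' The common inhibitory motoneurons are active during stepping epochs
#' (abolishing the slow fibres' residual stiffness, fully in swing and down
#' to a small fraction in stance) and inactive from the onset of a stop
#' command until the next start command, which reactivates them
#' immediately.
#'
#' @param stop_active Logical.
#' @return Logical: common inhibitor active?
#' @export
ci_state <- function(stop_active) !isTRUE(stop_active)
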