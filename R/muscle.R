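#' Per-muscle parameter set
#'
#' Extracts the kinetic, stiffness, recruitment and geometric parameters of
#' one muscle/fibre-class combination from a configuration.
#'
#' @param muscle One of `"protractor"`, `"retractor"`, `"levator"`,
#'   `"depressor"`, `"extensor"`, `"flexor"`.
#' @param fibre_class `"fast"` or `"slow"`.
#' @param cfg A [leg_config()].
#' @return A list of class `"muscle_params"`: activation rate constants per
#'   phase (slow rates derived as fast/100), relaxation rate, maximal active
#'   spring constant, stationary residual spring constant (0 for fast
#'   fibres), geometry (slope, anchor angle, minimal length, moment arm,
#'   contraction direction) and the control recruitment level.
#' @export
muscle_params <- function(muscle, fibre_class = c("fast", "slow"),
                          cfg = leg_config()) {
  muscle <- match.arg(muscle, MUSCLES)
  fibre_class <- match.arg(fibre_class)
  m <- cfg$muscle; g <- cfg$geometry
  div <- if (fibre_class == "slow") slow_rate_divisor() else 1
  structure(list(
    muscle = muscle,
    fibre_class = fibre_class,
    act_rate_stance = m$act_rate_stance[[muscle]] / div,
    act_rate_swing = m$act_rate_swing[[muscle]] / div,
    relax_rate = m$relax_rate,
    k_max = if (fibre_class == "fast") m$k_max_fast[[muscle]]
            else m$k_max_slow[[muscle]],
    k_res_stat = if (fibre_class == "fast") 0 else m$k_res[[muscle]],
    slope = g$slope[[muscle]],
    anchor = g$anchor[[muscle]],
    l_min = g$l_min[[muscle]],
    moment_arm = g$moment_arm[[muscle]],
    dir = g$dir[[muscle]],
    r_c = m$recruitment_ref
  ), class = "muscle_params")
}

#' Advance muscle activation by one step
#'
#' First-order activation kinetics: `dA/dt = k_act(phase) * (1 - A)` while
#' the motoneuron is spiking (within an action-potential window), and
#' `dA/dt = -k_r * A` otherwise.  The update is the exact solution of the
#' linear equation over the step, so it is unconditionally stable for the
#' very large fast-fibre rate constants.
#'
#' @param A Current activation in `[0, 1]` (vectorised).
#' @param params A [muscle_params()] object.
#' @param mn_spiking Logical: is the step inside an action-potential window?
#' @param phase `"stance"` or `"swing"` (selects the rate constant).
#' @param dt Step (ms), in `(0, 1]`.
#' @return Updated activation, clamped to `[0, 1]`.
#' @export
activation_step <- function(A, params, mn_spiking, phase = c("stance", "swing"),
                            dt) {
  phase <- match.arg(phase)
  if (!is.numeric(dt) || dt <= 0 || dt > 1)
    stop("dt must be in (0, 1] ms", call. = FALSE)
  k_act <- if (phase == "stance") params$act_rate_stance else params$act_rate_swing
  out <- vapply(A, cpp_activation_update, numeric(1),
                in_window = isTRUE(mn_spiking), k_act = k_act,
                k_r = params$relax_rate, dt = dt)
  pmin(pmax(out, 0), 1)
}

#' Actual residual stiffness of a muscle
#'
#' Implements the three-branch gating of the slow-fibre residual spring
#' constant by the common inhibitory motoneurons: zero for fast fibres
#' always; during stepping (common inhibitor active) zero in the swing
#' phase and a small fraction `f_stance` of the stationary value in the
#' stance phase; the full stationary value once a stop command has
#' inhibited the common inhibitor (until the next start command).
#'
#' @param params A [muscle_params()] object.
#' @param ci_active Logical: is the common inhibitory motoneuron active
#'   (true during stepping epochs, false from stop onset to start onset)?
#' @param phase `"stance"` or `"swing"`: the phase of this muscle's system,
#'   classified from its CPG membrane potential via [classify_cpg_phase()].
#' @param f_stance Stance-phase fraction of the stationary residual value.
#' @return The residual spring constant (mN/mm^2).
#' @export
residual_stiffness <- function(params, ci_active, phase = c("stance", "swing"),
                               f_stance = leg_config()$rules$f_stance) {
  phase <- match.arg(phase)
  cpp_residual_stiffness(params$fibre_class == "fast", isTRUE(ci_active),
                         phase == "stance", params$k_res_stat, f_stance)
}

#' Total spring constant of a muscle
#'
#' `k_total = k_max * A + k_res_actual`: the activation-dependent active
#' stiffness plus the gated residual stiffness (zero for fast fibres).
#' Recruitment scales the whole spring constant downstream, via
#' [effective_spring_constant()].
#'
#' @param params A [muscle_params()] object.
#' @param A Activation in `[0, 1]`.
#' @param k_res_actual Current residual stiffness from
#'   [residual_stiffness()].
#' @return Spring constant (mN/mm^2).
#' @export
total_stiffness <- function(params, A, k_res_actual) {
  stopifnot(A >= 0, A <= 1)
  cpp_total_stiffness(params$k_max, A, k_res_actual)
}

#' Effective spring constant at a recruitment level
#'
#' The spring constant corrected for the actual level of recruitment:
#' `k_eff = (r / r_c) * k`.
#'
#' @param k Spring constant (mN/mm^2).
#' @param r Actual recruitment level, `0 < r <= r_c`.
#' @param r_c Control (reference) recruitment level.
#' @return `k * r / r_c`.
#' @export
effective_spring_constant <- function(k, r, r_c = 1) {
  if (any(r <= 0) || any(r_c <= 0))
    stop("recruitment levels must be positive", call. = FALSE)
  if (any(r > r_c))
    stop("recruitment level r exceeds the reference level r_c", call. = FALSE)
  (r / r_c) * k
}

#' Muscle length from a joint angle
#'
#' Linear length-angle map `l = l_min + slope * d`, where `d` is the
#' angular distance from the muscle's slack anchor, signed so that the
#' muscle shortens when its action moves the joint (clamped at `l_min`).
#' The two members of an antagonistic pair have equal and opposite slopes,
#' so their lengths sum to a constant.
#'
#' @param angle Joint angle (deg), vectorised.
#' @param params A [muscle_params()] object.
#' @return Muscle length (mm).
#' @export
length_from_angle <- function(angle, params) {
  params$l_min + vapply(angle, cpp_muscle_stretch, numeric(1),
                        slope = params$slope, anchor = params$anchor,
                        dir = params$dir)
}

#' Spring force of a muscle
#'
#' `force = k_eff * max(l - l_min, 0)` with
#' `k_eff = (r / r_c) * k_total`: muscles only pull, and a muscle at or
#' below its minimal length is slack.
#'
#' @param params A [muscle_params()] object.
#' @param k_total Spring constant from [total_stiffness()].
#' @param length Muscle length (mm).
#' @param r Actual recruitment level (defaults to full recruitment).
#' @return Force (mN), never negative.
#' @export
muscle_force <- function(params, k_total, length, r = params$r_c) {
  stopifnot(length >= 0)
  stretch <- max(length - params$l_min, 0)
  cpp_muscle_force(k_total, r, params$r_c, stretch)
}

#' Recruitment levels for a commanded stationary angle
#'
#' Solves the static residual-stiffness balance of an antagonistic pair for
#' the recruitment levels that make the commanded angle stationary.  The
#' balance at the target is
#' `k_eff_1 * (l_1 - l_min_1) = k_eff_2 * (l_2 - l_min_2)` with
#' `k_eff_i = (r_i / r_c) * k_res_i`; the side that would overpower is
#' de-recruited and the other kept at the reference level, so at least one
#' member of the returned pair equals `r_c`.
#'
#' @param alpha_target Commanded stationary angle (deg).
#' @param agonist,antagonist [muscle_params()] of the pair (slow fibres).
#' @return Named vector `c(r_agonist, r_antagonist)` (fractions of `r_c`).
#'   An error is raised if either muscle is slack at the target (the target
#'   is then unreachable by de-recruitment because force cannot go
#'   negative).
#' @export
#' @examples
#' cfg <- leg_config()
#' pro <- muscle_params("protractor", "slow", cfg)
#' ret <- muscle_params("retractor", "slow", cfg)
#' recruitment_for_target_angle(95, pro, ret)
recruitment_for_target_angle <- function(alpha_target, agonist, antagonist) {
  st1 <- length_from_angle(alpha_target, agonist) - agonist$l_min
  st2 <- length_from_angle(alpha_target, antagonist) - antagonist$l_min
  if (st1 <= 0 || st2 <= 0) {
    slack <- if (st1 <= 0) agonist$muscle else antagonist$muscle
    stop("target angle ", alpha_target, " deg is unreachable: the ",
         slack, " is slack there (length at its minimum), so no positive ",
         "recruitment can balance the pair", call. = FALSE)
  }
  rr <- cpp_recruit_pair(agonist$k_res_stat, st1, antagonist$k_res_stat, st2)
  stats::setNames(rr * c(agonist$r_c, antagonist$r_c),
                  c(agonist$muscle, antagonist$muscle))
}

#' Static balance angle of an antagonistic pair
#'
#' Root of the residual-stiffness balance
#' `r_1 k_1 (l_1(theta) - l_min_1) - r_2 k_2 (l_2(theta) - l_min_2) = 0`,
#' found numerically.  Used as the independent prediction of passive
#' steady-state joint angles.
#'
#' @param agonist,antagonist [muscle_params()] of the pair.
#' @param r1,r2 Recruitment levels.
#' @param interval Search interval (deg).
#' @return The balance angle (deg).
#' @export
static_balance_angle <- function(agonist, antagonist, r1 = 1, r2 = 1,
                                 interval = c(10, 170)) {
  f <- function(th) {
    s1 <- length_from_angle(th, agonist) - agonist$l_min
    s2 <- length_from_angle(th, antagonist) - antagonist$l_min
    effective_spring_constant(agonist$k_res_stat, r1, agonist$r_c) * s1 -
      effective_spring_constant(antagonist$k_res_stat, r2, antagonist$r_c) * s2
  }
  uniroot(f, interval, tol = 1e-12)$root
}
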