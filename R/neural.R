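#' Construct a half-centre CPG unit
#'
#' A pair of mutually inhibitory two-variable neurons (persistent inward
#' current with slow inactivation, leak, constant excitatory drive, graded
#' synaptic inhibition from the partner).  With the default constants the
#' free-running pair produces a stable anti-phase rhythm with a period of
#' about 800 ms.
#'
#' @param g_drive_a,g_drive_b Drive conductances (uS) of the two neurons;
#'   constant over any simulation run (CPG autonomy).
#' @param g_inh_mutual Mutual-inhibition conductance (uS).
#' @param V_thr Phase-classification threshold (mV).
#' @param tau_scale Multiplier on the slow-variable time constant (sets the
#'   free-running period).
#' @param state Numeric `c(V_a, h_a, V_b, h_b)` initial state.
#' @param cfg A [leg_config()] supplying the shared neuron constants.
#' @return An object of class `"cpg_unit"`.
#' @export
cpg_unit <- function(g_drive_a = NULL, g_drive_b = NULL, g_inh_mutual = NULL,
                     V_thr = NULL, tau_scale = 1,
                     state = c(-20, 0.2, -60, 0.8), cfg = leg_config()) {
  cp <- cfg$cpg
  pars <- .flatten_params(cfg)$cpg
  pars[["tau_hbar"]] <- pars[["tau_hbar"]] * tau_scale
  structure(list(
    pars = pars,
    g_drive_a = if (is.null(g_drive_a)) cp$g_drive_a[["PR"]] else g_drive_a,
    g_drive_b = if (is.null(g_drive_b)) cp$g_drive_b[["PR"]] else g_drive_b,
    g_inh_mutual = if (is.null(g_inh_mutual)) cp$g_inh_mutual[["PR"]] else g_inh_mutual,
    V_thr = if (is.null(V_thr)) cp$V_thr else V_thr,
    state = state
  ), class = "cpg_unit")
}

#' Advance a CPG unit one integration step
#'
#' One fixed RK4 step of the half-centre pair.  A sensory pulse perturbs a
#' neuron's drive transiently (an additive conductance for this step only);
#' the stored drive conductances are never modified.
#'
#' @param unit A [cpg_unit()].
#' @param sensory_pulse Numeric `c(a, b)`: additive drive conductance (uS)
#'   applied to each neuron during this step; may be negative.
#' @param dt Step (ms) in `(0, 1]`.
#' @return The unit with advanced `state`.
#' @export
cpg_step <- function(unit, sensory_pulse = c(0, 0), dt = 0.1) {
  if (!is.numeric(dt) || dt <= 0 || dt > 1)
    stop("dt must be in (0, 1] ms", call. = FALSE)
  unit$state <- cpp_cpg_step(unit$pars, unit$state,
                             unit$g_drive_a, unit$g_drive_b,
                             unit$g_inh_mutual,
                             sensory_pulse[1], sensory_pulse[2], dt)
  unit
}

#' Free-run (or pulse) a CPG unit
#'
#' Integrates the pair for a given duration; optional per-step pulse
#' conductance traces drive phase resets.
#'
#' @param unit A [cpg_unit()].
#' @param duration Duration (ms).
#' @param dt Step (ms).
#' @param pulse_a,pulse_b Scalar or per-step additive drive conductances.
#' @return A matrix with columns `V_a`, `h_a`, `V_b`, `h_b` (one row per
#'   step, including the initial state) and attribute `dt`.
#' @export
cpg_free_run <- function(unit, duration, dt = 0.1, pulse_a = 0, pulse_b = 0) {
  n <- as.integer(round(duration / dt))
  out <- cpp_cpg_run(unit$pars, unit$state, unit$g_drive_a, unit$g_drive_b,
                     unit$g_inh_mutual, pulse_a, pulse_b, dt, n)
  attr(out, "dt") <- dt
  out
}

#' Classify a CPG phase from a membrane potential
#'
#' A sufficiently hyperpolarized pattern-generator neuron marks the swing
#' phase of its system; at or above the threshold the system is classified
#' stance-like (the tie is stance-like, so a borderline potential never
#' abolishes the stance-phase residual stiffness).
#'
#' @param V_CN Membrane potential (mV), vectorised.
#' @param V_thr Classification threshold (mV).
#' @return Character vector, `"swing"` or `"stance"`.
#' @export
classify_cpg_phase <- function(V_CN, V_thr = leg_config()$cpg$V_thr) {
  stopifnot(all(is.finite(V_CN)), is.finite(V_thr))
  ifelse(V_CN < V_thr, "swing", "stance")
}

#' Update an inhibitory interneuron relay
#'
#' The relays between the CPGs and the motoneuron pools transmit the
#' rhythmic CPG inhibition gradedly.  An enhanced central inhibitory
#' conductance onto the relay silences it, which disinhibits its target
#' (slow) motoneuron pool regardless of the CPG phase.
#'
#' @param cpg_inhibition CPG-driven inhibition in `[0, 1]`.
#' @param central_level `"normal"` or `"enhanced"`.
#' @return The relay output (inhibition delivered to the target pool) in
#'   `[0, 1]`: equal to `cpg_inhibition` at the normal central level, and 0
#'   when the central level is enhanced.
#' @export
interneuron_update <- function(cpg_inhibition,
                               central_level = c("normal", "enhanced")) {
  central_level <- match.arg(central_level)
  stopifnot(all(cpg_inhibition >= 0), all(cpg_inhibition <= 1))
  if (central_level == "enhanced") rep(0, length(cpg_inhibition))
  else cpg_inhibition
}

#' Graded synaptic activation of a presynaptic voltage
#'
#' The sigmoid gate used both for mutual CPG inhibition and for the
#' CPG-to-relay drive; relay inhibition of a motoneuron pool equals the
#' gate of the antagonist-driving CPG neuron.
#'
#' @param V Presynaptic membrane potential (mV).
#' @param cfg A [leg_config()].
#' @return Gate value in `(0, 1)`.
#' @export
synaptic_gate <- function(V, cfg = leg_config()) {
  1 / (1 + exp(-(V - cfg$cpg$syn_half) / cfg$cpg$syn_slope))
}

#' Construct a motoneuron pool
#'
#' A leaky integrate-and-fire unit with refractory period standing for one
#' motoneuron pool (one muscle, one fibre class).  Uninhibited it fires
#' tonically under its constant common drive; relay inhibition gates it
#' rhythmically (fast pools during stepping) or silences it.
#'
#' @param fibre_class `"fast"` or `"slow"`.
#' @param muscle_target One of the six muscle names.
#' @param g_common Common excitatory drive conductance (uS); defaults to
#'   the configured value for the fibre class.
#' @param cfg A [leg_config()].
#' @return An object of class `"motoneuron_pool"`.
#' @export
motoneuron_pool <- function(fibre_class = c("fast", "slow"),
                            muscle_target = MUSCLES, g_common = NULL,
                            cfg = leg_config()) {
  fibre_class <- match.arg(fibre_class)
  muscle_target <- match.arg(muscle_target)
  mn <- cfg$motoneuron
  structure(list(
    fibre_class = fibre_class,
    muscle_target = muscle_target,
    pars = .flatten_params(cfg)$mn,
    g_common = if (!is.null(g_common)) g_common
               else if (fibre_class == "fast") mn$g_common_fast
               else mn$g_common_slow,
    g_inh = mn$g_inh,
    V = mn$E_leak
  ), class = "motoneuron_pool")
}

#' Run a motoneuron pool against a relay-output trace
#'
#' Integrates the pool for `length(relay)` steps; the relay output in
#' `[0, 1]` scales the inhibitory conductance.  Spike times are recorded
#' for the muscle-activation windows.
#'
#' @param pool A [motoneuron_pool()].
#' @param relay Per-step relay output (inhibition) in `[0, 1]`.
#' @param dt Step (ms) in `(0, 1]`.
#' @return A list with the voltage trace `V` (length `length(relay) + 1`)
#'   and the spike times `spikes` (ms).
#' @export
motoneuron_run <- function(pool, relay, dt = 0.1) {
  if (!is.numeric(dt) || dt <= 0 || dt > 1)
    stop("dt must be in (0, 1] ms", call. = FALSE)
  stopifnot(all(relay >= 0), all(relay <= 1))
  cpp_mn_run(pool$pars, pool$V, relay, pool$g_common, pool$g_inh, dt)
}

#' Advance a motoneuron pool one step
#'
#' @param pool A [motoneuron_pool()].
#' @param relay_output Relay inhibition in `[0, 1]` for this step.
#' @param dt Step (ms) in `(0, 1]`.
#' @return The pool with updated membrane potential and a `spiked` flag.
#' @export
motoneuron_step <- function(pool, relay_output, dt = 0.1) {
  out <- motoneuron_run(pool, relay_output, dt)
  pool$V <- out$V[2]
  pool$spiked <- length(out$spikes) > 0
  pool
}
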