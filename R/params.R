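#' Activation rate constants of the fast muscle fibres
#'
#' Published per-muscle activation rate constants (1/ms) of the fast fibre
#' class, separately for the stance and the swing phase of the stepping
#' cycle.  The corresponding slow-fibre rates are always derived as one
#' hundredth of these values and are never stored independently.
#'
#' @return A data frame with columns `muscle`, `stance`, `swing` (1/ms).
#' @export
#' @examples
#' muscle_activation_rates()
muscle_activation_rates <- function() {
  data.frame(
    muscle = MUSCLES,
    stance = c(2.01, 5.01, 15.01, 5.01, 5.01, 8.01),
    swing  = c(0.81, 0.71, 8.01, 5.01, 5.01, 8.01),
    stringsAsFactors = FALSE
  )
}

#' Residual spring constants of the slow muscle fibres
#'
#' Published stationary residual stiffness (spring constant, mN/mm^2) of the
#' slow fibre class of each muscle.  Fast fibres have no residual stiffness.
#'
#' @return A data frame with columns `muscle` and `k_res` (mN/mm^2).
#' @export
#' @examples
#' muscle_residual_stiffness()
muscle_residual_stiffness <- function() {
  data.frame(
    muscle = MUSCLES,
    k_res = c(15.0, 25.5, 10.0, 8.8, 34.0, 4.3),
    stringsAsFactors = FALSE
  )
}

#' Ratio of fast to slow activation rate constants
#' @return The scalar 100: slow-fibre activation rates are this factor
#'   smaller than the fast-fibre rates of the same muscle and phase.
#' @export
slow_rate_divisor <- function() 100

# natural balance angle of a residual-stiffness pair with linear geometry
.natural_balance <- function(k1, a1, k2, a2) (k1 * a1 + k2 * a2) / (k1 + k2)

#' Build a simulation configuration
#'
#' Returns the full, validated parameter tree of the model, with every value
#' set to its packaged default.  Defaults fall into three provenance
#' classes (see [param_provenance()]): values printed in the source tables
#' (activation rates, residual stiffness, the 100x slow-rate rule), values
#' the companion neuron/muscle model would supply but that are chosen here
#' (neuron constants, relaxation rate, geometry), and pure implementation
#' choices (integrator step, trace stride).
#'
#' @param ... Named overrides.  Top-level names must match configuration
#'   sections (`sim`, `commands`, `init`, `cpg`, `motoneuron`, `muscle`,
#'   `geometry`, `joints`, `rules`); each override is merged into the
#'   defaults and re-validated.  Unknown names are an error.
#' @return A nested list of class `"leg_config"`.
#' @export
#' @examples
#' cfg <- leg_config()
#' cfg$muscle$act_rate_stance[["protractor"]]   # 2.01 / ms
#' cfg2 <- leg_config(sim = list(duration = 4000))
leg_config <- function(...) {
  tab1 <- muscle_activation_rates()
  tab2 <- muscle_residual_stiffness()
  nm <- function(x) stats::setNames(x, MUSCLES)

  anchor_e <- 55
  gamma_s <- 90
  # flexor anchor placed so the residual extensor/flexor balance sits at the
  # resting flexion angle
  anchor_f <- gamma_s + tab2$k_res[5] * (gamma_s - anchor_e) / tab2$k_res[6]
  anchors <- nm(c(5, 160, 95, 5, anchor_e, anchor_f))
  alpha_s <- .natural_balance(tab2$k_res[1], anchors[[1]],
                              tab2$k_res[2], anchors[[2]])

  cfg <- list(
    sim = list(
      dt = 0.1,            # integrator step (ms), fixed-step RK4
      duration = 10000,    # ms
      stride = 10L,        # trace sampling stride (samples every stride*dt)
      seed = 1L            # used only by fixture generation
    ),
    commands = data.frame(
      time = c(3000, 6500),
      command = c("stop", "start"),
      alpha_s = c(NA_real_, NA_real_),
      stringsAsFactors = FALSE
    ),
    init = list(
      angles = c(alpha = 80, beta = 30, gamma = 100),
      start_at_rest = FALSE
    ),
    cpg = list(
      # two-variable persistent-inward-current relaxation oscillator per
      # neuron; mutual graded inhibition within each half-centre pair
      C = 0.021, g_nap = 0.0028, g_leak = 0.0028,
      E_na = 50, E_leak = -65, E_syn = -80, E_drive = 0,
      m_half = -40, m_slope = 6, h_half = -48, h_slope = 6,
      tau_h_max = 1650, tau_h_half = -48, tau_h_slope = 12,
      syn_half = -45, syn_slope = 2,
      # per-system drive conductances (uS); constant over any run
      g_drive_a = c(PR = 3.5e-4, LD = 3.5e-4, EF = 3.5e-4),
      g_drive_b = c(PR = 3.5e-4, LD = 3.5e-4, EF = 3.5e-4),
      g_inh_mutual = c(PR = 0.004, LD = 0.004, EF = 0.004),
      # PR and EF run slightly slower free so the beta-crossing pulses,
      # not the intrinsic escape, time their phase transitions
      tau_scale = c(PR = 1.3, LD = 1, EF = 1.3),
      V_thr = -50,          # phase-classification threshold (mV)
      # start triggers: 90% of the free-running voltage range above rest
      trig_C1 = -23.7, trig_C3 = -23.7, trig_C6 = -23.7,
      pulse_g = 5e-3,       # sensory pulse conductance (uS)
      pulse_width = 20      # sensory pulse duration (ms)
    ),
    motoneuron = list(
      # leaky integrate-and-fire pools with refractory period
      C = 0.1, g_leak = 0.01, E_leak = -60, E_ex = 0, E_in = -80,
      V_spike = -45, V_reset = -60, refractory = 2,
      g_common_fast = 0.08,  # common excitatory drive, fast pools (uS)
      g_common_slow = 0.004, # common excitatory drive, slow pools (uS)
      g_inh = 0.2,           # relay inhibition conductance at output 1 (uS)
      fast_reduced_factor = 0,  # drive factor once a fast gate has closed
      slow_boost_factor = 20,   # drive factor while a slow pool is enhanced
      ap_window = 2          # activation window opened per spike (ms)
    ),
    muscle = list(
      act_rate_stance = nm(tab1$stance),   # fast fibres, 1/ms
      act_rate_swing = nm(tab1$swing),     # fast fibres, 1/ms
      relax_rate = 0.005,                  # shared by fast and slow fibres
      k_max_fast = nm(c(10, 10, 8, 16, 20, 2)),  # mN/mm^2
      k_max_slow = nm(tab2$k_res),               # mN/mm^2
      k_res = nm(tab2$k_res),                    # slow fibres only
      recruitment_ref = 1                  # control recruitment level r_c
    ),
    geometry = list(
      # linear length-angle maps; antagonist slopes are equal and opposite
      # so pair lengths sum to a constant
      slope = nm(rep(0.05, 6)),    # mm/deg
      anchor = anchors,            # angle (deg) at which the muscle is slack
      l_min = nm(rep(2, 6)),       # fully relaxed length (mm)
      moment_arm = nm(rep(1, 6)),  # mm
      # +1: muscle contraction increases its joint angle
      dir = nm(c(-1, 1, 1, -1, -1, 1))
    ),
    joints = list(
      inertia = c(ThC = 100, CTr = 37.5, FTi = 100),
      damping = c(ThC = 400, CTr = 150, FTi = 400),
      angle_min = c(ThC = 30, CTr = 10, FTi = 40),
      angle_max = c(ThC = 150, CTr = 95, FTi = 160)
    ),
    rules = list(
      beta_crit_PR = 45,   # levation angle triggering PR phase switches
      beta_crit_EF = 55,   # levation angle triggering EF phase switches
      hysteresis = 0.5,    # deg, debounce of threshold crossings
      beta_gc = 34,        # ground-contact levation angle (deg)
      eps_beta = 1.5,      # deg
      eps_angle = 2,       # deg
      eps_velocity = 0.05, # deg/ms
      alpha_crit = 104,    # swing-first vs stance-first boundary (deg)
      f_stance = 0.1,      # stance-phase fraction of the residual stiffness
      alpha_s = alpha_s,   # default commanded stationary ThC angle (deg)
      gamma_s = gamma_s,   # stationary FTi angle (deg)
      levdep_slow_tonic = FALSE,  # negative-result variant: tonic LD slow MNs
      slow_stop_mode = "enhanced" # "enhanced" (default) or "cut" (ablation)
    )
  )
  class(cfg) <- "leg_config"
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("overrides must be named", call. = FALSE)
    bad <- setdiff(names(overrides), names(unclass(cfg)))
    if (length(bad))
      stop("unknown configuration section(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    for (sec in names(overrides)) {
      if (sec == "commands") {
        cfg[[sec]] <- overrides[[sec]]
      } else {
        unknown <- setdiff(names(overrides[[sec]]), names(cfg[[sec]]))
        if (length(unknown))
          stop("unknown field(s) in '", sec, "': ",
               paste(unknown, collapse = ", "), call. = FALSE)
        cfg[[sec]] <- modifyList(cfg[[sec]], overrides[[sec]])
      }
    }
  }
  validate_config(cfg)
}

#' Validate a configuration
#'
#' Checks types, ranges and cross-field invariants of a `leg_config`,
#' including the fibre-class invariants (positive rates, residual stiffness
#' confined to slow fibres) and schedule alternation.  Called by
#' [leg_config()] and [load_config()].
#'
#' @param cfg A `leg_config` object or a bare nested list with the same
#'   structure.
#' @return The validated configuration (invisibly classed `"leg_config"`).
#' @export
validate_config <- function(cfg) {
  fail <- function(path, msg) stop("config field ", path, ": ", msg, call. = FALSE)
  num1 <- function(x, path, lo = -Inf, hi = Inf) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
      fail(path, "must be a single finite number")
    if (x < lo || x > hi) fail(path, sprintf("must be in [%g, %g]", lo, hi))
  }
  num1(cfg$sim$dt, "sim/dt", 1e-4, 1)
  num1(cfg$sim$duration, "sim/duration", cfg$sim$dt, Inf)
  if (cfg$sim$stride < 1) fail("sim/stride", "must be >= 1")

  cmd <- cfg$commands
  if (nrow(cmd)) {
    if (!all(cmd$command %in% c("stop", "start")))
      fail("commands/command", "must be 'stop' or 'start'")
    if (is.unsorted(cmd$time)) fail("commands/time", "must be non-decreasing")
    runs <- rle(cmd$command)$lengths
    if (any(runs > 1))
      fail("commands", "stop and start commands must alternate")
  }

  for (f in c("act_rate_stance", "act_rate_swing", "k_max_fast",
              "k_max_slow", "k_res")) {
    v <- cfg$muscle[[f]]
    if (length(v) != 6 || !all(is.finite(v)))
      fail(paste0("muscle/", f), "must be six finite values")
    if (startsWith(f, "act_rate") && any(v <= 0))
      fail(paste0("muscle/", f), "rates must be positive")
    if (startsWith(f, "k_") && any(v < 0))
      fail(paste0("muscle/", f), "stiffness must be non-negative")
  }
  num1(cfg$muscle$relax_rate, "muscle/relax_rate", 1e-6, 10)
  num1(cfg$muscle$recruitment_ref, "muscle/recruitment_ref", 1e-9, Inf)

  g <- cfg$geometry
  if (!all(g$slope > 0)) fail("geometry/slope", "must be positive")
  if (!all(g$dir %in% c(-1, 1))) fail("geometry/dir", "must be +1 or -1")
  # antagonist pairs must have opposite contraction directions
  if (any(g$dir[c(1, 3, 5)] * g$dir[c(2, 4, 6)] != -1))
    fail("geometry/dir", "antagonist pairs must have opposite signs")

  r <- cfg$rules
  num1(r$hysteresis, "rules/hysteresis", 0, 10)
  num1(r$eps_beta, "rules/eps_beta", 1e-9, Inf)
  num1(r$eps_angle, "rules/eps_angle", 1e-9, Inf)
  num1(r$eps_velocity, "rules/eps_velocity", 1e-9, Inf)
  if (!r$slow_stop_mode %in% c("enhanced", "cut"))
    fail("rules/slow_stop_mode", "must be 'enhanced' or 'cut'")
  for (f in c("beta_crit_PR", "beta_crit_EF", "beta_gc")) {
    num1(r[[f]], paste0("rules/", f),
         cfg$joints$angle_min[["CTr"]], cfg$joints$angle_max[["CTr"]])
  }
  if (!all(cfg$cpg$g_drive_a > 0) || !all(cfg$cpg$g_drive_b > 0))
    fail("cpg/g_drive", "drive conductances must be positive")
  class(cfg) <- "leg_config"
  invisible(cfg)
}

#' @export
print.leg_config <- function(x, ...) {
  cat("<leg_config>\n")
  cat(sprintf("  dt %.3g ms, duration %g ms, trace stride %d\n",
              x$sim$dt, x$sim$duration, x$sim$stride))
  if (nrow(x$commands)) {
    cat("  commands:\n")
    for (i in seq_len(nrow(x$commands)))
      cat(sprintf("    %6.0f ms  %-5s%s\n", x$commands$time[i],
                  x$commands$command[i],
                  ifelse(is.na(x$commands$alpha_s[i]), "",
                         sprintf("  alpha_s = %.4g", x$commands$alpha_s[i]))))
  } else cat("  commands: none (free stepping)\n")
  cat(sprintf("  stationary targets: alpha_s %.4g, gamma_s %.4g, beta_gc %.4g\n",
              x$rules$alpha_s, x$rules$gamma_s, x$rules$beta_gc))
  invisible(x)
}

#' Provenance of every configuration field
#'
#' Each default is tagged `"paper"` (a printed table value or rule),
#' `"companion"` (determined by the companion neuron/muscle model and chosen
#' here because its printed value is not available), or `"implementer"`
#' (pure implementation choice).
#'
#' @return A data frame with columns `field` and `provenance`.
#' @export
param_provenance <- function() {
  p <- function(field, prov) data.frame(field = field, provenance = prov,
                                        stringsAsFactors = FALSE)
  rbind(
    p("muscle/act_rate_stance", "paper"),
    p("muscle/act_rate_swing", "paper"),
    p("muscle/k_res", "paper"),
    p("muscle/slow_rate_divisor", "paper"),
    p("muscle/relax_rate", "companion"),
    p("muscle/k_max_fast", "companion"),
    p("muscle/k_max_slow", "companion"),
    p("muscle/recruitment_ref", "implementer"),
    p("cpg/*", "companion"),
    p("motoneuron/*", "companion"),
    p("geometry/*", "companion"),
    p("joints/*", "companion"),
    p("rules/beta_crit_PR", "companion"),
    p("rules/beta_crit_EF", "companion"),
    p("rules/beta_gc", "companion"),
    p("rules/eps_beta", "companion"),
    p("rules/eps_angle", "companion"),
    p("rules/eps_velocity", "companion"),
    p("rules/alpha_crit", "companion"),
    p("rules/f_stance", "companion"),
    p("rules/alpha_s", "companion"),
    p("rules/gamma_s", "companion"),
    p("sim/*", "implementer"),
    p("commands/*", "implementer"),
    p("init/*", "implementer")
  )
}

# ---- flattening for the compiled core ------------------------------------

# slow activation rates are derived here, never stored
.flatten_params <- function(cfg) {
  m <- cfg$muscle; g <- cfg$geometry; j <- cfg$joints; r <- cfg$rules
  cp <- cfg$cpg; mn <- cfg$motoneuron
  div <- slow_rate_divisor()
  list(
    cpg = c(C = cp$C, gnap = cp$g_nap, gl = cp$g_leak, Ena = cp$E_na,
            El = cp$E_leak, Esyn = cp$E_syn, Edrive = cp$E_drive,
            mhalf = cp$m_half, mk = cp$m_slope, hhalf = cp$h_half,
            hk = cp$h_slope, tau_hbar = cp$tau_h_max,
            tau_half = cp$tau_h_half, tau_k = cp$tau_h_slope,
            syn_half = cp$syn_half, syn_k = cp$syn_slope),
    tau_scale = unname(cp$tau_scale),
    g_drive_a = unname(cp$g_drive_a),
    g_drive_b = unname(cp$g_drive_b),
    g_inh_mutual = unname(cp$g_inh_mutual),
    V_thr = cp$V_thr, trig_C1 = cp$trig_C1, trig_C3 = cp$trig_C3,
    trig_C6 = cp$trig_C6,
    pulse_g = cp$pulse_g, pulse_width = cp$pulse_width,
    mn = c(C = mn$C, gl = mn$g_leak, El = mn$E_leak, Eex = mn$E_ex,
           Ein = mn$E_in, thr = mn$V_spike, reset = mn$V_reset,
           refr = mn$refractory),
    g_common = c(rep(mn$g_common_fast, 6), rep(mn$g_common_slow, 6)),
    g_inh_mn = mn$g_inh,
    fast_reduced_factor = mn$fast_reduced_factor,
    slow_boost_factor = mn$slow_boost_factor,
    ap_window = mn$ap_window,
    act_rate_stance = unname(c(m$act_rate_stance, m$act_rate_stance / div)),
    act_rate_swing = unname(c(m$act_rate_swing, m$act_rate_swing / div)),
    relax_rate = rep(m$relax_rate, 12),
    k_max = unname(c(m$k_max_fast, m$k_max_slow)),
    k_res_stat = unname(c(rep(0, 6), m$k_res)),
    recruitment = rep(m$recruitment_ref, 12),
    recruitment_ref = rep(m$recruitment_ref, 12),
    slope = unname(g$slope), anchor = unname(g$anchor),
    l_min = unname(g$l_min), arm = unname(g$moment_arm),
    dir = unname(g$dir),
    inertia = unname(j$inertia), damping = unname(j$damping),
    angle_lo = unname(j$angle_min), angle_hi = unname(j$angle_max),
    beta_crit_pr = r$beta_crit_PR, beta_crit_ef = r$beta_crit_EF,
    hysteresis = r$hysteresis, beta_gc = r$beta_gc,
    eps_beta = r$eps_beta, eps_angle = r$eps_angle,
    eps_vel = r$eps_velocity,
    alpha_crit = r$alpha_crit, f_stance = r$f_stance,
    levdep_slow_tonic = as.integer(isTRUE(r$levdep_slow_tonic)),
    slow_stop_mode = if (identical(r$slow_stop_mode, "cut")) 1L else 0L,
    alpha_s = r$alpha_s, gamma_s = r$gamma_s
  )
}

# numeric command schedule for the core: code 1 = stop, 2 = start
.flatten_schedule <- function(cfg) {
  cmd <- cfg$commands
  if (is.null(cmd) || nrow(cmd) == 0)
    return(matrix(numeric(0), 0, 3))
  cbind(cmd$time, ifelse(cmd$command == "stop", 1, 2),
        ifelse(is.na(cmd$alpha_s), NA_real_, cmd$alpha_s))
}

# initial CPG state: synchronized stance (C1, C4, C6 active)
.cpg_init_state <- function() {
  c(-20, 0.2, -60, 0.8,    # C1 active, C2 silent
    -60, 0.8, -20, 0.2,    # C3 silent, C4 active
    -60, 0.8, -20, 0.2)    # C5 silent, C6 active
}
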