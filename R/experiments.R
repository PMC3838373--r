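#' Generate standard experiment configurations
#'
#' Deterministic (seeded) families of configurations implementing the
#' standard experiments at desk scale:
#' \describe{
#'   \item{`"stop-sweep"`}{20 configurations differing only in the time of
#'     the stop command, spread uniformly over one stepping cycle (the
#'     common base phase is drawn from the seed).}
#'   \item{`"start-modes"`}{Three configurations commanding stationary
#'     retraction angles below, at and above the critical angle, each with
#'     a stop command followed by a start command, so that both the
#'     reached posture and the restart mode can be measured.}
#'   \item{`"slow-boost-ablation"`}{Pairs of configurations identical
#'     except for the slow-motoneuron stop behaviour: enhanced tonic
#'     firing (default) versus pools cut at the stop command.  Stop times
#'     are jittered over the cycle by the seed, one pair per seed draw.}
#' }
#'
#' @param kind Experiment family.
#' @param seed Integer seed; the family is a deterministic function of it.
#' @param cfg Base configuration.
#' @param n Number of configurations (`"stop-sweep"`: phases;
#'   `"slow-boost-ablation"`: pairs).  Ignored for `"start-modes"`.
#' @return A named list of `leg_config` objects.
#' @export
#' @examples
#' length(make_fixture("stop-sweep", seed = 1, n = 5))
make_fixture <- function(kind = c("stop-sweep", "start-modes",
                                  "slow-boost-ablation"),
                         seed = 1L, cfg = leg_config(), n = NULL) {
  kind <- match.arg(kind)
  period <- 798  # free-running stepping period under the default drives
  set.seed(as.integer(seed))
  out <- list()
  if (kind == "stop-sweep") {
    if (is.null(n)) n <- 20L
    base <- 2400 + stats::runif(1, 0, period / n)
    times <- base + (seq_len(n) - 1) * period / n
    for (i in seq_len(n)) {
      ci <- cfg
      ci$commands <- data.frame(time = times[i], command = "stop",
                                alpha_s = NA_real_)
      ci$sim$duration <- times[i] + 4000
      out[[sprintf("stop_phase_%02d", i)]] <- validate_config(ci)
    }
  } else if (kind == "start-modes") {
    targets <- cfg$rules$alpha_crit + c(-8, 0, 8)
    for (i in seq_along(targets)) {
      ci <- cfg
      ci$commands <- data.frame(time = c(2700, 7000),
                                command = c("stop", "start"),
                                alpha_s = c(targets[i], NA_real_))
      ci$sim$duration <- 10000
      out[[sprintf("alpha_s_%g", targets[i])]] <- validate_config(ci)
    }
  } else {
    if (is.null(n)) n <- 10L
    times <- 2400 + stats::runif(n, 0, period)
    for (i in seq_len(n)) {
      for (mode in c("enhanced", "cut")) {
        ci <- cfg
        ci$commands <- data.frame(time = times[i], command = "stop",
                                  alpha_s = NA_real_)
        ci$sim$duration <- times[i] + 6000
        ci$rules$slow_stop_mode <- mode
        out[[sprintf("pair_%02d_%s", i, mode)]] <- validate_config(ci)
      }
    }
  }
  out
}

#' Run a stop-phase sweep
#'
#' Simulates stop commands at `n` uniformly spread phases of one stepping
#' cycle and summarises each run: final angles, whether and when the
#' permanent ground contact latched, the time of full rest, and the
#' direction of the final retraction-angle excursion.
#'
#' @param seed Seed for [make_fixture()].
#' @param n Number of phases.
#' @param cfg Base configuration.
#' @return A data frame with one row per stop phase.
#' @export
stop_sweep <- function(seed = 1L, n = 20L, cfg = leg_config()) {
  cfgs <- make_fixture("stop-sweep", seed = seed, cfg = cfg, n = n)
  do.call(rbind, lapply(seq_along(cfgs), function(i) {
    sim <- leg_simulate(cfgs[[i]])
    tr <- sim$trace
    fin <- tr[nrow(tr), ]
    latch_t <- sim$events$time[sim$events$event == "ground_contact_latch"][1]
    vel <- pmax(abs(tr$alpha_dot), abs(tr$beta_dot), abs(tr$gamma_dot))
    rest_t <- if (any(vel >= 1e-3)) tr$t[max(which(vel >= 1e-3)) + 1] else tr$t[1]
    moving <- which(abs(tr$alpha_dot) > 0.02)
    data.frame(
      stop_time = cfgs[[i]]$commands$time[1],
      final_alpha = fin$alpha, final_beta = fin$beta, final_gamma = fin$gamma,
      latch_time = latch_t, rest_time = rest_t,
      latched_before_rest = !is.na(latch_t) && latch_t <= rest_t,
      final_alpha_excursion = if (length(moving))
        c("protraction", "retraction")[(sign(tr$alpha_dot[max(moving)]) + 1) / 2 + 1]
        else "none",
      max_residual_velocity = max(abs(unlist(
        fin[c("alpha_dot", "beta_dot", "gamma_dot")])))
    )
  }))
}

#' Run the posture / start-mode experiment
#'
#' Three commanded stationary retraction angles (below, at and above the
#' critical angle) are each reached by a stop command and then released by
#' a start command.  Returns the recruitment-predicted and realised
#' postures and the observed restart mode.
#'
#' @param seed Seed for [make_fixture()].
#' @param cfg Base configuration.
#' @return A data frame with one row per target.
#' @export
posture_experiment <- function(seed = 1L, cfg = leg_config()) {
  cfgs <- make_fixture("start-modes", seed = seed, cfg = cfg)
  do.call(rbind, lapply(cfgs, function(ci) {
    sim <- leg_simulate(ci)
    tr <- sim$trace
    ev <- sim$events
    t_start <- ci$commands$time[2]
    pre <- tr[tr$t >= t_start - 500 & tr$t < t_start, ]
    target <- ci$commands$alpha_s[1]
    mode_code <- ev$value[ev$event == "start_mode_selected"][1]
    en <- ev[ev$event %in% c("PR_enabled", "EF_enabled", "LD_enabled"), ]
    t_en <- min(en$time)
    post <- tr[tr$t >= t_en, ]
    i_mv <- which(abs(post$alpha_dot) > 0.02 | abs(post$beta_dot) > 0.02 |
                    abs(post$gamma_dot) > 0.02)[1]
    first_move <- if (is.na(i_mv)) NA_character_ else {
      v <- c(abs(post$alpha_dot[i_mv]), abs(post$beta_dot[i_mv]),
             abs(post$gamma_dot[i_mv]))
      c("alpha", "beta", "gamma")[which.max(v)]
    }
    data.frame(
      alpha_target = target,
      rest_alpha = mean(pre$alpha), rest_beta = mean(pre$beta),
      rest_gamma = mean(pre$gamma),
      posture_error = abs(mean(pre$alpha) - target),
      start_mode = c("swing-first", "stance-first")[mode_code + 1],
      first_moving_angle = first_move,
      liftoff_time = post$t[post$beta > ci$rules$beta_gc + 2][1]
    )
  }))
}

#' Paired slow-motoneuron ablation runs
#'
#' For each seeded stop time, simulates the stop once with the default
#' enhanced tonic slow-motoneuron activity and once with the slow PR and
#' EF pools cut at the command, and measures the convergence time of the
#' retraction angle to its stationary value in both.
#'
#' @param seed Seed.
#' @param n Number of pairs.
#' @param cfg Base configuration.
#' @param tolerance Convergence band around the stationary angle (deg).
#' @return A data frame with columns `stop_time`, `t_boost`, `t_cut` (ms
#'   from the stop command) and `boost_faster`.
#' @export
slow_boost_experiment <- function(seed = 1L, n = 10L, cfg = leg_config(),
                                  tolerance = 0.5) {
  cfgs <- make_fixture("slow-boost-ablation", seed = seed, cfg = cfg, n = n)
  idx <- seq(1, length(cfgs), by = 2)
  do.call(rbind, lapply(idx, function(i) {
    conv <- function(ci) {
      sim <- leg_simulate(ci)
      tr <- sim$trace
      t0 <- ci$commands$time[1]
      convergence_time(tr$t, tr$alpha, ci$rules$alpha_s, tolerance) - t0
    }
    t_boost <- conv(cfgs[[i]])
    t_cut <- conv(cfgs[[i + 1]])
    data.frame(stop_time = cfgs[[i]]$commands$time[1],
               t_boost = t_boost, t_cut = t_cut,
               boost_faster = t_boost < t_cut)
  }))
}
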