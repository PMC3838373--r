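# shared simulation cache: expensive runs are computed once per test session
.sim_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .sim_cache))
    assign(name, force(expr), envir = .sim_cache)
  get(name, envir = .sim_cache)
}

default_sim <- function() cached("default_sim", leg_simulate(leg_config()))

short_cfg <- function(duration = 3000, commands = NULL) {
  cfg <- leg_config(sim = list(duration = duration))
  if (!is.null(commands)) cfg$commands <- commands
  else cfg$commands <- cfg$commands[0, ]
  validate_config(cfg)
}

# free stepping, no commands
stepping_sim <- function() cached("stepping_sim", leg_simulate(short_cfg(4000)))

# one stop command mid-cycle, long enough to reach full rest
stop_sim <- function() cached("stop_sim", leg_simulate(short_cfg(
  9000, data.frame(time = 2700, command = "stop", alpha_s = NA_real_))))

sweep_results <- function() cached("sweep_results", stop_sweep(seed = 1, n = 20))

sweep_sims <- function() cached("sweep_sims", {
  cfgs <- make_fixture("stop-sweep", seed = 1, n = 20)
  lapply(cfgs, leg_simulate)
})

startmode_sims <- function() cached("startmode_sims", {
  cfgs <- make_fixture("start-modes", seed = 1)
  lapply(cfgs, leg_simulate)
})

boost_results <- function() cached("boost_results",
                                   slow_boost_experiment(seed = 1, n = 10))

# rest-state relaxation (no commands, start latched at rest): passive
# residual-stiffness equilibrium
rest_sim <- function() cached("rest_sim", {
  cfg <- short_cfg(4000)
  cfg$init$start_at_rest <- TRUE
  cfg$init$angles <- c(alpha = 70, beta = 34, gamma = 120)
  leg_simulate(cfg)
})
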