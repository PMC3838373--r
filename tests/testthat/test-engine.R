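test_that("free stepping has the swing = levation + protraction + extension structure", {
  sim <- stepping_sim()
  tr <- sim$trace
  steady <- tr[tr$t > 1200, ]
  # sustained periodic stepping in all three angles
  for (a in c("alpha", "beta", "gamma"))
    expect_gt(diff(range(steady[[a]])), 10)
  # during swing (leg lifted) alpha decreases (protraction) and gamma
  # decreases (extension) on average; during stance the reverse
  swing <- steady$beta > sim$config$rules$beta_crit_PR + 5
  stance <- steady$beta < sim$config$rules$beta_gc
  expect_lt(mean(steady$alpha_dot[swing]), 0)
  expect_lt(mean(steady$gamma_dot[swing]), 0)
  expect_gt(mean(steady$alpha_dot[stance]), 0)
  expect_gt(mean(steady$gamma_dot[stance]), 0)
  # alternation: stance and swing interval counts differ by at most one
  ph <- extract_phases(sim, "leg")
  n_sw <- sum(ph$phase == "swing"); n_st <- sum(ph$phase == "stance")
  expect_lte(abs(n_sw - n_st), 1)
  expect_gt(n_sw, 2)
})

test_that("extension starts later and ends earlier than protraction", {
  sim <- stepping_sim()
  ev <- sim$events
  up_pr <- ev$time[ev$event == "beta_cross_PR_up"]
  up_ef <- ev$time[ev$event == "beta_cross_EF_up"]
  dn_pr <- ev$time[ev$event == "beta_cross_PR_down"]
  dn_ef <- ev$time[ev$event == "beta_cross_EF_down"]
  n <- min(length(up_pr), length(up_ef))
  expect_true(all(up_pr[1:n] < up_ef[1:n]))   # protraction first on the way up
  n <- min(length(dn_pr), length(dn_ef))
  expect_true(all(dn_ef[1:n] < dn_pr[1:n]))   # extension finishes earlier
})

test_that("identical configurations yield byte-identical runs", {
  cfg <- short_cfg(1500)
  s1 <- leg_simulate(cfg)
  s2 <- leg_simulate(cfg)
  expect_identical(s1$trace, s2$trace)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$spikes, s2$spikes)
})

test_that("a stop command brings the leg to rest at the commanded posture", {
  sim <- stop_sim()
  tr <- sim$trace
  fin <- tr[nrow(tr), ]
  expect_lt(max(abs(unlist(fin[c("alpha_dot", "beta_dot", "gamma_dot")]))),
            1e-4)
  expect_lt(abs(fin$alpha - sim$config$rules$alpha_s), 0.05)
  expect_identical(fin$beta, sim$config$rules$beta_gc)
  expect_lt(abs(fin$gamma - sim$config$rules$gamma_s), 0.05)
  expect_identical(fin$latch, 1)
})

test_that("trace invariants hold throughout a stop/start run", {
  sim <- default_sim()
  tr <- sim$trace
  expect_true(all(is.finite(as.matrix(tr))))
  A <- as.matrix(tr[grep("^A_", names(tr))])
  expect_true(all(A >= 0 & A <= 1))
  expect_true(all(as.matrix(tr[grep("^force_", names(tr))]) >= 0))
  j <- sim$config$joints
  expect_true(all(tr$alpha >= j$angle_min[["ThC"]] & tr$alpha <= j$angle_max[["ThC"]]))
  expect_true(all(tr$beta >= j$angle_min[["CTr"]] & tr$beta <= j$angle_max[["CTr"]]))
  expect_true(all(tr$gamma >= j$angle_min[["FTi"]] & tr$gamma <= j$angle_max[["FTi"]]))
  # commands are mutually exclusive at every sample
  expect_true(all(tr$stop_active + tr$start_active <= 1))
  # each gate switches through its levels monotonically within the stop epoch
  stop_rows <- tr$stop_active == 1
  expect_true(all(diff(tr$gate_slow_PR[stop_rows]) >= 0))
  expect_true(all(diff(tr$gate_slow_EF[stop_rows]) >= 0))
})

test_that("residual-stiffness gating replays bit-exactly from the logged phases", {
  sim <- default_sim()
  tr <- sim$trace
  cfg <- sim$config
  f <- cfg$rules$f_stance
  phase_col <- c(protractor = "phase_PR", retractor = "phase_PR",
                 levator = "phase_LD", depressor = "phase_LD",
                 extensor = "phase_EF", flexor = "phase_EF")
  for (m in c("retractor", "extensor", "levator")) {
    p <- muscle_params(m, "slow", cfg)
    replay <- mapply(function(ci, ph)
      residual_stiffness(p, ci == 1, if (ph == 1) "stance" else "swing", f),
      tr$ci_active, tr[[phase_col[[m]]]])
    expect_identical(replay, tr[[paste0("k_res_slow_", m)]])
  }
})

test_that("total stiffness replays bit-exactly from logged activation and residuals", {
  sim <- default_sim()
  tr <- sim$trace
  cfg <- sim$config
  for (m in c("protractor", "flexor")) {
    pf <- muscle_params(m, "fast", cfg)
    replay <- vapply(seq_len(nrow(tr)), function(i)
      total_stiffness(pf, tr[[paste0("A_fast_", m)]][i], 0), numeric(1))
    expect_identical(replay, tr[[paste0("k_total_fast_", m)]])
  }
})

test_that("phase extraction recovers constructed boundaries and handles degenerate traces", {
  t <- seq(0, 4000, by = 1)
  tr <- data.frame(
    t = t,
    alpha = 90 + 20 * sin(2 * pi * t / 800),
    beta = 50 + 25 * sin(2 * pi * t / 800 + pi / 2),
    gamma = 95 + 15 * sin(2 * pi * t / 800),
    alpha_dot = 20 * 2 * pi / 800 * cos(2 * pi * t / 800),
    beta_dot = -25 * 2 * pi / 800 * sin(2 * pi * t / 800),
    gamma_dot = 15 * 2 * pi / 800 * cos(2 * pi * t / 800)
  )
  ph <- extract_phases(tr, "PR", min_duration = 100, vel_eps = 0.01)
  # boundaries of the alpha velocity sign changes: at t = 200 + k*400
  analytic <- 200 + 400 * (0:9)
  for (b in ph$start[-1])
    expect_lt(min(abs(b - analytic)), 25)
  expect_setequal(unique(ph$phase), c("retraction", "protraction"))

  const <- tr; const$alpha_dot <- 0; const$beta_dot <- 0; const$gamma_dot <- 0
  expect_identical(nrow(extract_phases(const, "PR")), 0L)
})

test_that("convergence time matches the analytic crossing for exponential decay", {
  t <- seq(0, 2000, by = 1)
  y <- 10 * exp(-t / 300)
  # |y| < 0.5 from t = 300 * log(20)
  expect_equal(convergence_time(t, y, 0, 0.5), ceiling(300 * log(20)),
               tolerance = 1)
  expect_message(ct <- convergence_time(t, sin(t / 50), 0, 0.5), "not converged")
  expect_identical(ct, NA_real_)
})

test_that("halving the integration step leaves the end-state angles unchanged", {
  cfg1 <- short_cfg(5500, data.frame(time = 2700, command = "stop",
                                     alpha_s = NA_real_))
  cfg2 <- cfg1
  cfg2$sim$dt <- 0.05
  cfg2$sim$stride <- 20L
  f1 <- tail(leg_simulate(cfg1)$trace, 1)
  f2 <- tail(leg_simulate(cfg2)$trace, 1)
  expect_lt(max(abs(unlist(f1[c("alpha", "beta", "gamma")]) -
                    unlist(f2[c("alpha", "beta", "gamma")]))), 0.1)
})

test_that("trace export and JSON summary are written and re-readable", {
  sim <- stepping_sim()
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_trace(sim, f)
  re <- read.csv(f)
  expect_identical(dim(re), dim(sim$trace))
  expect_equal(re$alpha, sim$trace$alpha, tolerance = 1e-10)
  j <- tempfile(fileext = ".json")
  on.exit(unlink(j), add = TRUE)
  summary_json(sim, j)
  parsed <- jsonlite::read_json(j)
  expect_true(all(c("final", "cpg_period", "events", "phases") %in% names(parsed)))
})

test_that("the rest state holds passively at the static-balance posture", {
  sim <- rest_sim()
  tr <- sim$trace
  fin <- tr[nrow(tr), ]
  cfg <- sim$config
  pro <- muscle_params("protractor", "slow", cfg)
  ret <- muscle_params("retractor", "slow", cfg)
  ext <- muscle_params("extensor", "slow", cfg)
  flx <- muscle_params("flexor", "slow", cfg)
  expect_lt(abs(fin$alpha - static_balance_angle(pro, ret, interval = c(30, 150))),
            1e-3)
  expect_lt(abs(fin$gamma - static_balance_angle(ext, flx, interval = c(56, 160))),
            1e-3)
  expect_identical(fin$beta, cfg$rules$beta_gc)
})
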