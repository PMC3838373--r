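cfg <- leg_config()

test_that("activation decays with the closed-form exponential when silent", {
  p <- muscle_params("protractor", "fast", cfg)
  A <- 0.5
  dt <- 0.1
  for (i in 1:1000) A <- activation_step(A, p, FALSE, "stance", dt)
  expect_equal(A, 0.5 * exp(-p$relax_rate * 100), tolerance = 1e-12)
})

test_that("sustained spiking drives activation monotonically to one", {
  p <- muscle_params("retractor", "fast", cfg)
  A <- numeric(200); a <- 0
  for (i in seq_along(A)) A[i] <- a <- activation_step(a, p, TRUE, "stance", 0.1)
  expect_true(all(diff(A) >= 0))
  expect_gt(A[200], 0.999)
  expect_lte(A[200], 1)
})

test_that("slow fibres activate one hundred times slower than fast fibres", {
  # identical sustained excitation into the fast and the slow protractor:
  # time to half activation scales exactly with the rate divisor
  t_half <- function(p) {
    a <- 0; t <- 0; dt <- 0.1
    repeat {
      a1 <- activation_step(a, p, TRUE, "swing", dt)
      if (a1 >= 0.5)  # linear interpolation inside the bracketing step
        return(t + dt * (0.5 - a) / (a1 - a))
      a <- a1; t <- t + dt
    }
  }
  tf <- t_half(muscle_params("protractor", "fast", cfg))
  ts <- t_half(muscle_params("protractor", "slow", cfg))
  expect_equal(ts / tf, 100, tolerance = 0.02)
  # and the packaged rate constants obey the divisor exactly, per muscle and phase
  fp <- .flatten_params(cfg)
  expect_identical(fp$act_rate_stance[7:12], fp$act_rate_stance[1:6] / 100)
  expect_identical(fp$act_rate_swing[7:12], fp$act_rate_swing[1:6] / 100)
})

test_that("residual stiffness follows the three-branch common-inhibitor gating", {
  ext <- muscle_params("extensor", "slow", cfg)
  f <- cfg$rules$f_stance
  # stepping, swing phase: vanishes
  expect_identical(residual_stiffness(ext, ci_active = TRUE, "swing", f), 0)
  # stepping, stance phase: small fraction of the stationary value
  expect_identical(residual_stiffness(ext, ci_active = TRUE, "stance", f),
                   f * 34.0)
  # post-stop steady state: full stationary value
  expect_identical(residual_stiffness(ext, ci_active = FALSE, "stance", f), 34.0)
  expect_identical(residual_stiffness(ext, ci_active = FALSE, "swing", f), 34.0)
  # fast fibres never have residual stiffness
  extf <- muscle_params("extensor", "fast", cfg)
  expect_identical(residual_stiffness(extf, TRUE, "stance", f), 0)
  expect_identical(residual_stiffness(extf, FALSE, "stance", f), 0)
})

test_that("total and effective spring constants combine as specified", {
  slow <- muscle_params("extensor", "slow", cfg)
  fast <- muscle_params("extensor", "fast", cfg)
  # absence of action potentials, steady state: residual only
  expect_identical(total_stiffness(slow, 0, slow$k_res_stat), 34.0)
  expect_identical(total_stiffness(fast, 0, 0), 0)
  # full recruitment, full activation
  expect_identical(total_stiffness(slow, 1, 17), slow$k_max + 17)

  expect_identical(effective_spring_constant(34.0, 1, 1), 34.0)
  expect_identical(effective_spring_constant(34.0, 0.5, 1), 17.0)
  expect_lt(effective_spring_constant(34.0, 1e-12, 1), 1e-9)
  expect_error(effective_spring_constant(10, 1.2, 1), "exceeds")
  expect_error(effective_spring_constant(10, -1, 1), "positive")
})

test_that("muscle force is a clamped spring: slack below minimal length", {
  p <- muscle_params("extensor", "slow", cfg)
  expect_identical(muscle_force(p, 34.0, p$l_min), 0)
  expect_identical(muscle_force(p, 34.0, p$l_min - 0.5), 0)
  expect_identical(muscle_force(p, 34.0, p$l_min + 1), 34.0)
  # force is never negative over a range of lengths and stiffness values
  for (l in seq(0, 10, by = 0.5))
    expect_gte(muscle_force(p, 12.3, l), 0)
})

test_that("recruitment solves the stationary balance and one side stays at r_c", {
  pro <- muscle_params("protractor", "slow", cfg)
  ret <- muscle_params("retractor", "slow", cfg)
  balance <- static_balance_angle(pro, ret, interval = c(30, 150))
  # at the natural balance angle no de-recruitment is needed
  r0 <- recruitment_for_target_angle(balance, pro, ret)
  expect_equal(unname(r0), c(1, 1), tolerance = 1e-12)

  imbalance <- function(target, r) {
    s1 <- length_from_angle(target, pro) - pro$l_min
    s2 <- length_from_angle(target, ret) - ret$l_min
    effective_spring_constant(pro$k_res_stat, r[1]) * s1 -
      effective_spring_constant(ret$k_res_stat, r[2]) * s2
  }
  for (target in c(70, 88, 96, 104, 112, 130)) {
    r <- recruitment_for_target_angle(target, pro, ret)
    expect_equal(max(r), 1)
    expect_true(all(r > 0 & r <= 1))
    # balance holds to < 1e-9 relative at the target
    scale <- ret$k_res_stat * (length_from_angle(target, ret) - ret$l_min)
    expect_lt(abs(imbalance(target, r)) / scale, 1e-9)
  }
})

test_that("recruitment agrees with a bisection oracle on the imbalance", {
  pro <- muscle_params("protractor", "slow", cfg)
  ret <- muscle_params("retractor", "slow", cfg)
  # oracle: bisect the de-recruited side's level until the static balance
  # holds at the target
  oracle <- function(target) {
    s1 <- length_from_angle(target, pro) - pro$l_min
    s2 <- length_from_angle(target, ret) - ret$l_min
    f1 <- pro$k_res_stat * s1; f2 <- ret$k_res_stat * s2
    if (f1 > f2) c(uniroot(function(r) r * f1 - f2, c(1e-9, 1), tol = 1e-14)$root, 1)
    else c(1, uniroot(function(r) f1 - r * f2, c(1e-9, 1), tol = 1e-14)$root)
  }
  for (target in c(75, 95, 115)) {
    expect_equal(unname(recruitment_for_target_angle(target, pro, ret)),
                 oracle(target), tolerance = 1e-9)
  }
})

test_that("targets where the de-recruited muscle goes slack are infeasible", {
  pro <- muscle_params("protractor", "slow", cfg)
  ret <- muscle_params("retractor", "slow", cfg)
  # at the protractor anchor the protractor is slack: no balance possible
  expect_error(recruitment_for_target_angle(pro$anchor, pro, ret),
               "unreachable")
  expect_error(recruitment_for_target_angle(ret$anchor + 1, pro, ret),
               "unreachable")
})

test_that("recruitment round-trip: the balance root returns the target", {
  pro <- muscle_params("protractor", "slow", cfg)
  ret <- muscle_params("retractor", "slow", cfg)
  set.seed(7)
  targets <- runif(50, 60, 140)
  for (target in targets) {
    r <- recruitment_for_target_angle(target, pro, ret)
    root <- static_balance_angle(pro, ret, r[[1]], r[[2]], c(30, 150))
    expect_lt(abs(root - target), 1e-6)
  }
})
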