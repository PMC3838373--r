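cfg <- leg_config()

test_that("length-angle maps anchor at l_min, are monotone, and pair-sums are constant", {
  for (pair in list(c("protractor", "retractor"), c("levator", "depressor"),
                    c("extensor", "flexor"))) {
    p1 <- muscle_params(pair[1], "fast", cfg)
    p2 <- muscle_params(pair[2], "fast", cfg)
    # at its own anchor a muscle is at minimal length
    expect_equal(length_from_angle(p1$anchor, p1), p1$l_min)
    expect_equal(length_from_angle(p2$anchor, p2), p2$l_min)
    set.seed(11)
    # angles within the overlap where neither muscle is clamped slack
    lo <- min(p1$anchor, p2$anchor); hi <- max(p1$anchor, p2$anchor)
    th <- runif(100, lo, hi)
    l1 <- length_from_angle(th, p1); l2 <- length_from_angle(th, p2)
    sums <- l1 + l2
    expect_lt(diff(range(sums)), 1e-9)
    # the angle-increasing muscle shortens with the angle, its antagonist lengthens
    o <- order(th)
    inc1 <- diff(l1[o])
    expect_true(all(inc1 <= 0) || all(inc1 >= 0))
  }
})

test_that("joint dynamics: rest without torque, terminal velocity under constant torque", {
  st <- list(angle = 90, angular_velocity = 0, joint_id = "ThC")
  for (i in 1:100) st <- joint_step(st, 0, 100, 400, 0.5)
  expect_equal(st$angle, 90)
  expect_equal(st$angular_velocity, 0)

  st <- list(angle = 40, angular_velocity = 0, joint_id = "ThC")
  for (i in 1:4000) st <- joint_step(st, 80, 100, 400, 0.5)
  expect_equal(st$angular_velocity, 80 / 400, tolerance = 1e-6)
})

test_that("a latched levation joint is held at the ground-contact angle", {
  st <- list(angle = 50, angular_velocity = 1, joint_id = "CTr")
  st <- joint_step(st, 500, 37.5, 150, 0.5,
                   contact = list(permanent_latch = TRUE), beta_gc = 34)
  expect_identical(st$angle, 34)
  expect_identical(st$angular_velocity, 0)
  expect_error(joint_step(st, Inf, 37.5, 150, 0.5), "non-finite")
})

test_that("a passive antagonistic pair settles at the static-balance root", {
  # 3 joints x several recruitment draws: the damped joint driven only by
  # the residual springs must come to rest at the balance-equation root
  pairs <- list(c("protractor", "retractor"), c("levator", "depressor"),
                c("extensor", "flexor"))
  joints <- c("ThC", "CTr", "FTi")
  intervals <- list(c(30, 150), c(11, 94), c(56, 160))
  set.seed(3)
  for (k in 1:3) {
    p1 <- muscle_params(pairs[[k]][1], "slow", cfg)
    p2 <- muscle_params(pairs[[k]][2], "slow", cfg)
    for (draw in 1:4) {
      r <- c(1, 1)
      r[sample(2, 1)] <- runif(1, 0.4, 1)
      root <- static_balance_angle(p1, p2, r[1], r[2], intervals[[k]])
      torque <- function(th) {
        f1 <- r[1] * p1$k_res_stat * max(length_from_angle(th, p1) - p1$l_min, 0)
        f2 <- r[2] * p2$k_res_stat * max(length_from_angle(th, p2) - p2$l_min, 0)
        p1$dir * p1$moment_arm * f1 + p2$dir * p2$moment_arm * f2
      }
      st <- list(angle = root + c(-15, 12)[draw %% 2 + 1],
                 angular_velocity = 0, joint_id = joints[k])
      for (i in 1:20000)
        st <- joint_step(st, torque, cfg$joints$inertia[[k]],
                         cfg$joints$damping[[k]], 0.5)
      # relative imbalance at the settled angle
      f2s <- r[2] * p2$k_res_stat * (length_from_angle(st$angle, p2) - p2$l_min)
      expect_lt(abs(torque(st$angle)) / abs(f2s), 1e-6)
      expect_lt(abs(st$angle - root), 1e-4)
    }
  }
})

test_that("beta threshold crossings are detected once each, in threshold order", {
  r <- cfg$rules
  t <- seq(0, 1000, by = 1)
  rising <- 20 + 0.06 * t           # monotone rise through both thresholds
  ev <- beta_sensory_events(t, rising, r)
  expect_identical(ev$system, c("PR", "EF"))
  expect_identical(ev$direction, c("up", "up"))
  expect_lt(ev$time[1], ev$time[2])  # protraction precedes extension

  # falling sweep: EF first (extension ends before protraction)
  ev2 <- beta_sensory_events(t, 80 - 0.06 * t, r)
  expect_identical(ev2$system, c("EF", "PR"))

  expect_identical(nrow(beta_sensory_events(t, rep(42, length(t)), r)), 0L)
})

test_that("sub-hysteresis jitter is debounced to one event per genuine crossing", {
  r <- cfg$rules
  t <- seq(0, 2000, by = 0.5)
  base <- 45 + 20 * sin(2 * pi * t / 1000)       # two genuine PR crossings/cycle
  jitter <- 0.3 * sin(2 * pi * t / 7)            # sub-hysteresis wiggle
  ev <- beta_sensory_events(t, base + jitter, r)
  pr <- ev[ev$system == "PR", ]
  # brute-force detector on the clean dense trace
  clean_up <- sum(diff(base > r$beta_crit_PR) == 1)
  clean_dn <- sum(diff(base > r$beta_crit_PR) == -1)
  expect_identical(sum(pr$direction == "up"), clean_up)
  expect_identical(sum(pr$direction == "down"), clean_dn)
})

test_that("the contact latch needs stop epoch, closed gates and the contact angle", {
  r <- cfg$rules
  up <- function(beta, beta_dot = -0.01, gates = TRUE, stop = TRUE,
                 contact = list(in_contact = FALSE, permanent_latch = FALSE))
    contact_update(beta, beta_dot, r, gates, stop, contact)
  expect_true(up(34)$permanent_latch)
  expect_true(up(34 + r$eps_beta)$permanent_latch)
  expect_false(up(34 + r$eps_beta + 0.01)$permanent_latch)  # beta off target
  expect_false(up(34, gates = FALSE)$permanent_latch)       # gates still open
  expect_false(up(34, stop = FALSE)$permanent_latch)        # no stop episode
  expect_false(up(34, beta_dot = 0.5)$permanent_latch)      # still rising
  # latch implies contact and persists
  c1 <- up(34)
  c2 <- contact_update(60, 1, r, FALSE, TRUE, c1)
  expect_true(c2$permanent_latch && c2$in_contact)
})
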