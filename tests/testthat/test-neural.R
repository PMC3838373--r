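test_that("free-running half-centre oscillates in stable anti-phase", {
  u <- cpg_unit()
  tr <- cpg_free_run(u, 8000, dt = 0.1)
  Va <- tr[, "V_a"]; Vb <- tr[, "V_b"]
  keep <- seq(20000, nrow(tr))   # discard transient
  thr <- u$V_thr
  # sustained oscillation
  on_a <- which(diff(Va[keep] > thr) == 1)
  expect_gt(length(on_a), 5)
  # period stable to < 1% across cycles
  per <- diff(on_a) * 0.1
  expect_lt(sd(per) / mean(per), 0.01)
  # anti-phase: simultaneous suprathreshold time well under 5% of samples
  overlap <- mean(Va[keep] > thr & Vb[keep] > thr)
  expect_lt(overlap, 0.05)
})

test_that("CPG period agrees with a ten-fold finer reference integration", {
  u <- cpg_unit()
  per_of <- function(dt) {
    tr <- cpg_free_run(u, 5000, dt = dt)
    on <- which(diff(tr[, "V_a"] > u$V_thr) == 1) * dt
    mean(diff(on[-1]))
  }
  expect_lt(abs(per_of(0.1) - per_of(0.01)) / per_of(0.01), 0.001)
})

test_that("zero drive leaves both neurons at rest", {
  u <- cpg_unit(g_drive_a = 1e-12, g_drive_b = 1e-12,
                state = c(-60, 0.8, -60, 0.8))
  tr <- cpg_free_run(u, 5000, dt = 0.1)
  keep <- seq(10000, nrow(tr))
  expect_true(all(tr[keep, "V_a"] < u$V_thr))
  expect_true(all(tr[keep, "V_b"] < u$V_thr))
  expect_lt(diff(range(tr[keep, "V_a"])), 0.5)
})

test_that("identical twin units produce bit-identical trajectories", {
  u1 <- cpg_unit(); u2 <- cpg_unit()
  t1 <- cpg_free_run(u1, 2000, dt = 0.1)
  t2 <- cpg_free_run(u2, 2000, dt = 0.1)
  expect_identical(t1, t2)
})

test_that("a sensory pulse switches the half-centre phase at once", {
  u <- cpg_unit()
  tr <- cpg_free_run(u, 3000, dt = 0.1)
  u$state <- tr[nrow(tr), ]  # some mid-cycle state
  active_a <- u$state[1] > u$state[3]
  n <- 3000
  pulse <- c(rep(leg_config()$cpg$pulse_g, 200), rep(0, n - 200))
  tr2 <- if (active_a) cpg_free_run(u, 300, dt = 0.1, pulse_b = pulse)
         else cpg_free_run(u, 300, dt = 0.1, pulse_a = pulse)
  Vt <- if (active_a) tr2[, "V_b"] else tr2[, "V_a"]
  expect_lt(which(Vt > u$V_thr)[1] * 0.1, 25)
})

test_that("phase classification is hyperpolarized-swing with stance tie-break", {
  expect_identical(classify_cpg_phase(-70, -50), "swing")
  expect_identical(classify_cpg_phase(-20, -50), "stance")
  expect_identical(classify_cpg_phase(-50, -50), "stance")
  expect_identical(classify_cpg_phase(c(-60, -40), -50), c("swing", "stance"))
  expect_error(classify_cpg_phase(NaN, -50))
})

test_that("interneuron relay passes CPG inhibition and is silenced when enhanced", {
  expect_equal(interneuron_update(1, "normal"), 1)
  expect_equal(interneuron_update(0, "normal"), 0)
  expect_equal(interneuron_update(0.37, "normal"), 0.37)
  for (inh in c(0, 0.5, 1))
    expect_equal(interneuron_update(inh, "enhanced"), 0)
  # monotone non-increasing firing in the delivered inhibition is checked in
  # the motoneuron gating test below
  expect_error(interneuron_update(1.5, "normal"))
})

test_that("motoneuron pools: full inhibition silences, constant drive is tonic", {
  pool <- motoneuron_pool("fast", "retractor")
  n <- 20000
  silent <- motoneuron_run(pool, rep(1, n), dt = 0.1)
  expect_length(silent$spikes, 0)

  tonic <- motoneuron_run(pool, rep(0, n), dt = 0.1)
  isi <- diff(tonic$spikes)
  expect_gt(length(tonic$spikes), 100)
  expect_lt(sd(isi) / mean(isi), 0.1)
})

test_that("motoneuron firing rate is non-increasing in relay output", {
  pool <- motoneuron_pool("fast", "retractor")
  rates <- vapply(seq(0, 1, by = 0.1), function(rel)
    length(motoneuron_run(pool, rep(rel, 10000), dt = 0.1)$spikes),
    numeric(1))
  expect_true(all(diff(rates) <= 0))
  expect_gt(rates[1], 0)
  expect_identical(rates[11], 0)
})

test_that("rhythmically gated motoneurons burst in the relay-low intervals", {
  pool <- motoneuron_pool("fast", "retractor")
  # square-wave relay: 300 ms on (inhibited), 300 ms off
  relay <- rep(rep(c(1, 0), each = 3000), 3)
  out <- motoneuron_run(pool, relay, dt = 0.1)
  phase <- (out$spikes %/% 300) %% 2   # 0: inhibited half, 1: released half
  expect_true(all(phase == 1))
  expect_gt(length(out$spikes), 50)
})
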