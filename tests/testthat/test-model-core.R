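# Single-neuron membrane and synaptic-gating kinetics.

test_that("membrane at rest with no input is a fixed point", {
  p <- neuron_params()
  st <- neuron_state(p$resting_potential)
  out <- step_membrane(st, p, 0, 0, dt = 0.05)
  expect_false(out$spiked)
  expect_equal(out$state$membrane_potential, p$resting_potential)
})

test_that("constant suprathreshold current reproduces the analytic ISI", {
  # closed form for reset at V_rest:
  #   T = tau_ref + (C/g_L) * log(I / (I - g_L (V_th - V_rest)))
  dt <- 0.02
  for (i_ext in c(1.4, 1.8, 2.5)) {
    p <- neuron_params(reset_potential = -70)  # reset at rest
    T_exact <- p$refractory_period +
      p$capacitance / p$leak_conductance *
      log(i_ext / (i_ext - p$leak_conductance *
                     (p$threshold - p$resting_potential)))
    st <- neuron_state(p$resting_potential)
    spikes <- numeric(0)
    for (k in seq_len(round(60 / dt))) {
      out <- step_membrane(st, p, 0, i_ext, dt)
      st <- out$state
      if (out$spiked) spikes <- c(spikes, k * dt)
    }
    expect_gt(length(spikes), 2)
    isi <- diff(spikes)
    expect_lt(max(abs(isi - T_exact)), 2 * dt)
  }
})

test_that("refractory neuron ignores huge input and stays at reset", {
  p <- neuron_params()
  st <- neuron_state(p$reset_potential, refractory_remaining = 1.5)
  out <- step_membrane(st, p, 1e3, 1e3, dt = 0.05)
  expect_false(out$spiked)
  expect_equal(out$state$membrane_potential, p$reset_potential)
  expect_equal(out$state$refractory_remaining, 1.45)
})

test_that("non-finite input aborts with a diagnostic", {
  p <- neuron_params()
  expect_error(step_membrane(neuron_state(-60), p, NaN, 0, 0.05),
               "non-finite")
  expect_error(step_membrane(neuron_state(Inf), p, 0, 0, 0.05),
               "non-finite")
})

test_that("silenced neuron relaxes to rest with tau_m = C/g_L", {
  p <- neuron_params()
  tau_m <- p$capacitance / p$leak_conductance
  dt <- 0.005
  st <- neuron_state(-60)
  for (k in seq_len(round(tau_m / dt)))  # integrate exactly one tau_m
    st <- step_membrane(st, p, 0, 0, dt)$state
  expected <- p$resting_potential + (-60 - p$resting_potential) * exp(-1)
  expect_equal(st$membrane_potential, expected, tolerance = 1e-3)
})

test_that("stepped spike times converge as dt halves (O(dt))", {
  p <- neuron_params(reset_potential = -70)
  first_spike <- function(dt) {
    st <- neuron_state(p$resting_potential)
    for (k in seq_len(round(40 / dt))) {
      out <- step_membrane(st, p, 0, 1.6, dt)
      st <- out$state
      if (out$spiked) return(k * dt)
    }
    NA_real_
  }
  t1 <- first_spike(0.1)
  t2 <- first_spike(0.05)
  t3 <- first_spike(0.025)
  expect_lt(abs(t2 - t3), abs(t1 - t3) + 1e-9)
  expect_lt(abs(t2 - t3), 3 * 0.05)
})

test_that("two-stage gating: zero is absorbing without input", {
  kin <- synapse_kinetics("AMPA")
  g <- list(x = 0, s = 0)
  for (k in 1:200) g <- update_gating_two_stage(g, FALSE, kin, 0.05)
  expect_equal(g$s, 0)
  expect_equal(g$x, 0)
})

test_that("two-stage gating after one spike decays with -1/tau_decay", {
  # oracle: dense-step reference integration at dt/100
  kin <- synapse_kinetics("NMDA")
  evolve <- function(dt, n) {
    g <- update_gating_two_stage(list(x = 0, s = 0), TRUE, kin, dt)
    s_trace <- numeric(n)
    for (k in seq_len(n)) {
      g <- update_gating_two_stage(g, FALSE, kin, dt)
      s_trace[k] <- g$s
    }
    s_trace
  }
  dt <- 0.05
  s_coarse <- evolve(dt, 8000)               # 400 ms
  s_dense <- evolve(dt / 100, 8000 * 100)
  expect_equal(s_coarse[8000], s_dense[8000 * 100], tolerance = 2e-2)
  # late-time log-slope equals -1/tau_decay
  late <- s_coarse[6000:8000]
  slope <- coef(lm(log(late) ~ seq_along(late)))[2] / dt
  expect_equal(unname(slope), -1 / kin$decay_time_constant,
               tolerance = 1e-2)
})

test_that("two-stage gating saturates below 1 for high-rate trains", {
  kin <- synapse_kinetics("AMPA")
  g <- list(x = 0, s = 0)
  for (k in 1:4000)  # a spike every step: 20 kHz, far beyond physiology
    g <- update_gating_two_stage(g, TRUE, kin, 0.05)
  expect_lt(g$s, 1)
  expect_gt(g$s, 0.9)
})

test_that("single-stage gating decays exponentially and is memoryless", {
  kin <- synapse_kinetics("GABA_slow", decay_time_constant = 100)
  s <- update_gating_single_stage(0, TRUE, kin, 0.05)   # jump to 1
  expect_equal(s, 1)
  for (k in 1:2000) s <- update_gating_single_stage(s, FALSE, kin, 0.05)
  expect_equal(s, exp(-100 / 100), tolerance = 1e-10)   # e^{-t/tau} at t=100
  # two spikes >> 5 tau apart give identical post-spike values
  s2 <- s
  for (k in 1:20000) s2 <- update_gating_single_stage(s2, FALSE, kin, 0.05)
  s2 <- update_gating_single_stage(s2, TRUE, kin, 0.05)
  expect_equal(s2, 1, tolerance = 1e-4)
})

test_that("periodic train reaches the fixed point of the jump-decay map", {
  # oracle: iterate the 1-d map s -> (s + j(1-s)) e^{-Delta/tau}
  kin <- synapse_kinetics("GABA_fast", decay_time_constant = 8, jump = 0.6)
  delta <- 12          # ms between spikes
  dt <- 0.05
  map <- function(s) (s + kin$jump * (1 - s)) * exp(-delta / kin$decay_time_constant)
  s_fix <- 0
  for (k in 1:500) s_fix <- map(s_fix)      # fixed-point iteration
  s <- 0
  n_per <- round(delta / dt)
  for (spk in 1:80) {
    s <- update_gating_single_stage(s, TRUE, kin, dt)
    for (k in seq_len(n_per - 1)) s <- update_gating_single_stage(s, FALSE, kin, dt)
  }
  # s is now the pre-spike value; discretisation shifts it by O(dt/tau)
  expect_equal(s, s_fix, tolerance = 2e-2)
})

test_that("synaptic current: zeros, reversal, and sign conventions", {
  g <- c(ampa = 0, nmda = 0, gaba_fast = 0, gaba_slow = 0)
  cond <- c(ampa = 0.03, nmda = 0.001, gaba_fast = 0.05, gaba_slow = 0.08)
  expect_equal(synaptic_current(g, cond, -60), 0)
  # at the class reversal potential the class contributes nothing
  expect_equal(synaptic_current(c(gaba_fast = 1), cond, -75), 0)
  # GABA above reversal is hyperpolarizing, glutamate at rest depolarizing
  expect_lt(synaptic_current(c(gaba_slow = 0.5), cond, -60), 0)
  expect_gt(synaptic_current(c(ampa = 0.5), cond, -70), 0)
  expect_gt(synaptic_current(c(nmda = 0.5), cond, -70), 0)
  expect_error(synaptic_current(c(gabab = 1), cond, -60), "unknown")
})

test_that("NMDA magnesium block is sigmoidal in voltage", {
  expect_lt(mg_block(-80), mg_block(-40))
  expect_equal(mg_block(-60, mg_conc = 0), 1)
  b <- mg_block(-65)
  expect_equal(b, 1 / (1 + exp(-0.062 * -65) / 3.57))
})
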