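# Wiring, simulation plumbing, determinism and the downstream readout.

test_that("bernoulli p = 1 wiring is all-to-all without autapses", {
  net <- build_network(tg_tiny_config(connectivity = "bernoulli", p = 1))
  for (src in c("e", "f", "s")) for (tgt in c("e", "f", "s")) {
    m <- net$adjacency[[paste0(src, tgt)]]
    if (src == tgt) {
      expect_true(all(diag(m) == 0))
      expect_true(all(m[row(m) != col(m)] == 1))
    } else {
      expect_true(all(m == 1))
    }
  }
})

test_that("bernoulli in-degrees match the binomial expectation", {
  # oracle: in-degree ~ Binomial(n_src, p); check the mean over targets
  # and seeds against p * n_src within a few standard errors
  p <- 0.8
  degs <- unlist(lapply(1:5, function(seed) {
    net <- build_network(network_config(connectivity = "bernoulli", p = p,
                                        seed = seed))
    colSums(net$adjacency$ef)   # EX -> INf, 100 sources x 50 targets
  }))
  n_src <- 100
  se <- sqrt(n_src * p * (1 - p) / length(degs))
  expect_lt(abs(mean(degs) - p * n_src), 4 * se)
})

test_that("invalid configurations are rejected", {
  expect_error(network_config(connectivity = "bernoulli", p = 0),
               "probability")
  expect_error(network_config(conductances = c(g_GAfe = -1)),
               "non-negative")
  expect_error(network_config(conductances = c(g_bogus = 0.1)),
               "unknown conductance")
  expect_error(network_config(n_ex = 0))
})

test_that("per-projection weights divide by (expected in-degree)", {
  cfg <- network_config()
  net <- build_network(cfg)
  expect_equal(unname(net$weights["am_ee"]),
               cfg$conductances[["g_AMee"]] / cfg$n_ex)
  expect_equal(unname(net$weights["ga_se"]),
               cfg$conductances[["g_GAse"]] / cfg$n_ins)
  netb <- build_network(network_config(connectivity = "bernoulli", p = 0.8))
  expect_equal(unname(netb$weights["am_ee"]), 0.03 / (0.8 * 100))
  netp <- build_network(network_config(conductance_scaling = "per_synapse"))
  expect_equal(unname(netp$weights["am_ee"]), 0.03)
})

test_that("identical config and seed give bit-identical spike rasters", {
  s1 <- tg_tiny_sim(seed = 7)
  s2 <- tg_tiny_sim(seed = 7)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$v_ex, s2$v_ex)
  s3 <- tg_tiny_sim(seed = 8)
  expect_false(identical(s1$spikes, s3$spikes))
})

test_that("compiled network matches the R reference dynamics", {
  # dual route: a 1/1/1 network with all couplings silenced must follow
  # the scalar step_membrane() semantics exactly
  g0 <- setNames(rep(0, 12), names(network_config()$conductances))
  cfg <- network_config(n_ex = 1, n_inf = 1, n_ins = 1, conductances = g0,
                        duration = 100, warmup = 0, record_dt = 0.05,
                        background = list(ex = 1.5, ex_heterogeneity = 0),
                        seed = 3)
  sim <- run_simulation(build_network(cfg), stimulus_protocol(amplitude = 0))
  p <- cfg$neuron_ex
  st <- neuron_state(sim$v_ex[1, 1])            # same initial condition
  v_ref <- numeric(nrow(sim$v_ex))
  v_ref[1] <- st$membrane_potential
  for (k in 2:length(v_ref)) {
    st <- step_membrane(st, p, 0, 1.5, cfg$dt)$state
    v_ref[k] <- st$membrane_potential
  }
  expect_equal(sim$v_ex[, 1], v_ref, tolerance = 1e-10)
})

test_that("silencing both inhibitory populations leaves no slow envelope", {
  cfg <- network_config(duration = 1600,
                        conductances = c(g_GAse = 0, g_GAfe = 0),
                        seed = 2)
  sim <- run_simulation(build_network(cfg),
                        stimulus_protocol(onset = 600, duration = 1000))
  spec <- morlet_transform(sim, seq(2, 20, by = 1))
  th <- band_mean_amplitude(spec, c(4, 8), c(600, 1600))$mean
  intact <- tg_test_sim()
  spec_i <- morlet_transform(intact, seq(2, 20, by = 1))
  th_i <- band_mean_amplitude(spec_i, c(4, 8), c(1000, 2000))$mean
  expect_lt(th, th_i / 3)
})

test_that("downstream neuron is silent without afferent spikes", {
  out <- downstream_response(numeric(0), duration = 500)
  expect_equal(out$rate, 0)
  expect_length(out$spike_times, 0)
})

test_that("downstream neuron fires for the nested-gamma regime", {
  sim <- tg_test_sim()
  out <- downstream_response(sim, window = c(1000, 2000))
  expect_gt(out$rate, 5)
})

test_that("background substream is independent of connectivity draws", {
  # adding the connectivity consumer must not perturb the backgrounds
  a2a <- run_simulation(build_network(tg_tiny_config(seed = 5)),
                        stimulus_protocol(onset = 200, duration = 200))
  sp <- run_simulation(
    build_network(tg_tiny_config(seed = 5, connectivity = "bernoulli",
                                 p = 0.9)),
    stimulus_protocol(onset = 200, duration = 200))
  expect_identical(a2a$v_ex[1, ], sp$v_ex[1, ])  # same initial state draw
})
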