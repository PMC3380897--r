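# KL phase-amplitude coupling: distributions, coherence, comodulograms.

test_that("KL coherence: uniform is exactly 0, delta exactly 1", {
  expect_identical(kl_coherence(rep(1 / 18, 18)), 0)
  expect_equal(kl_coherence(c(1, rep(0, 17))), 1)
  expect_error(kl_coherence(c(0.5, 0.2)), "sum")
})

test_that("KL coherence of a cosine-shaped distribution matches a direct sum", {
  n <- 18
  phi <- (seq_len(n) - 0.5) * 2 * pi / n
  for (m in c(0.25, 0.5, 0.9)) {
    p <- (1 + m * cos(phi)) / sum(1 + m * cos(phi))
    direct <- sum(p * log(p / (1 / n))) / log(n)     # independent summation
    expect_equal(kl_coherence(p), direct, tolerance = 1e-12)
  }
})

test_that("amplitude distribution: uniform, delta and modulated cases", {
  n <- 18
  phase <- runif(20000, 0, 2 * pi)
  d <- amplitude_distribution(phase, rep(2.5, length(phase)), n)
  expect_equal(d$p, rep(1 / n, n), tolerance = 1e-12)
  expect_equal(sum(d$p), 1)
  # amplitude 1 only when the phase is in bin 1
  in1 <- phase < 2 * pi / n
  d1 <- amplitude_distribution(phase, as.numeric(in1), n)
  expect_equal(d1$p[1], 1)
  expect_true(all(d1$p[-1] == 0))
  # sinusoidal modulation of depth m: oracle = direct binning at 10x bins
  m <- 0.5
  amp <- 1 + m * cos(phase)
  d2 <- amplitude_distribution(phase, amp, n)
  fine <- amplitude_distribution(phase, amp, 10 * n)
  coarse_from_fine <- colSums(matrix(fine$mean_amplitude, nrow = 10))
  expect_equal(d2$p, coarse_from_fine / sum(coarse_from_fine),
               tolerance = 2e-2)
  expect_error(amplitude_distribution(c(0.1, 0.2), c(1, 1), n), "empty")
})

test_that("bandpass pair: tone phase ramps and flat envelopes", {
  dt <- 1
  t <- seq(0, 5999) * dt / 1000
  bank <- filter_bank_spec()
  pr <- bandpass_pair(sin(2 * pi * 6 * t), dt, bank)
  i6 <- which(bank$phase_centers == 6)
  mid <- 1000:5000
  steps <- diff(pr$phase[mid, i6])
  ramp <- mean(steps[steps > -pi])
  expect_equal(ramp, 2 * pi * 6 / 1000, tolerance = 1e-3)
  pr45 <- bandpass_pair(0.7 * sin(2 * pi * 45 * t), dt, bank)
  i45 <- which(bank$amp_centers == 44)
  expect_equal(mean(pr45$amplitude[mid, i45]), 0.7, tolerance = 0.05)
  expect_lt(sd(pr45$amplitude[mid, i45]), 0.02)
})

test_that("comodulogram is bounded, scale- and offset-invariant", {
  sig <- generate_coupled_signal(coupled_signal_spec(m = 0.7, noise_sd = 0.3,
                                                     duration = 5000))$signal
  cm <- cfc_matrix(sig, dt = 1)
  expect_true(all(cm$matrix >= 0 & cm$matrix <= 1))
  expect_equal(cm$mean, mean(cm$matrix))
  cm2 <- cfc_matrix(5 * sig + 3, dt = 1)
  expect_equal(cm2$matrix, cm$matrix, tolerance = 1e-8)
})

test_that("coherence increases with fixture modulation depth", {
  vals <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(m) {
    sig <- generate_coupled_signal(coupled_signal_spec(
      m = m, noise_sd = 0.2, duration = 8000, seed = 11))$signal
    cfc_matrix(sig, dt = 1)$mean
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("matrix entries equal a naive three-loop implementation exactly", {
  sig <- generate_coupled_signal(coupled_signal_spec(m = 1, noise_sd = 0.1,
                                                     duration = 4000))$signal
  bank <- filter_bank_spec(phase_centers = c(5, 6, 7),
                           amp_centers = c(42, 44, 46))
  pair <- bandpass_pair(sig, 1, bank)
  cm <- cfc_matrix(sig, dt = 1, bank = bank, pair = pair)
  n_bins <- 18
  for (i in 1:3) for (j in 1:3) {                 # naive three-loop oracle
    sums <- numeric(n_bins); counts <- numeric(n_bins)
    for (k in seq_along(sig)) {
      b <- floor(pair$phase[k, i] / (2 * pi) * n_bins) + 1
      if (b > n_bins) b <- n_bins
      sums[b] <- sums[b] + pair$amplitude[k, j]
      counts[b] <- counts[b] + 1
    }
    p <- (sums / counts) / sum(sums / counts)
    kl <- sum(ifelse(p > 0, p * log(p * n_bins), 0)) / log(n_bins)
    expect_equal(cm$matrix[i, j], kl, tolerance = 1e-12)
  }
})

test_that("noise-free maximally modulated fixture peaks near its carriers", {
  sig <- generate_coupled_signal(coupled_signal_spec(m = 1, noise_sd = 0,
                                                     duration = 8000))$signal
  cm <- cfc_matrix(sig, dt = 1)
  pk <- which(cm$matrix == max(cm$matrix), arr.ind = TRUE)
  phase_pk <- as.numeric(rownames(cm$matrix))[pk[1]]
  amp_pk <- as.numeric(colnames(cm$matrix))[pk[2]]
  expect_lt(abs(phase_pk - 6), 2.1)
  expect_lt(abs(amp_pk - 45), 8.1)
})

test_that("white noise over a long window gives near-zero mean coherence", {
  # permutation-style null: compare against the same signal with the
  # amplitude series circularly shifted (destroys any true coupling)
  set.seed(9)
  noise <- rnorm(8000)
  bank <- filter_bank_spec(phase_centers = 4:8,
                           amp_centers = seq(34, 50, 4))
  cm <- cfc_matrix(noise, dt = 1, bank = bank)
  pair <- bandpass_pair(noise, 1, bank)
  null_vals <- vapply(c(997, 2003, 3001, 4999), function(shift) {
    shifted <- list(phase = pair$phase,
                    amplitude = pair$amplitude[c((shift + 1):8000, 1:shift), ,
                                               drop = FALSE])
    cfc_matrix(noise, dt = 1, bank = bank, pair = shifted)$mean
  }, numeric(1))
  expect_lt(cm$mean, max(null_vals) * 3 + 0.02)
  expect_lt(cm$mean, 0.05)
})

test_that("empty phase bins error by default and drop rows on request", {
  # a 2 Hz phase band observed for 0.4 s covers well under one cycle, so
  # some of the 18 phase bins must be empty
  t <- seq(0, 3.999, by = 0.001)
  sig <- sin(2 * pi * 2 * t) + 0.5 * sin(2 * pi * 42 * t)
  bank <- filter_bank_spec(phase_centers = 2, amp_centers = c(40, 44))
  expect_error(cfc_matrix(sig, dt = 1, bank = bank, window = c(0, 400)),
               "empty phase bin|too short")
  expect_warning(
    cm <- cfc_matrix(sig, dt = 1, bank = bank, window = c(0, 400),
                     on_empty = "na"),
    "row dropped")
  expect_true(all(is.na(cm$matrix)))
})
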