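# LFP construction, Morlet spectra, band amplitudes, phases, dispersion
# and nested-event counting.

test_that("LFP is the arithmetic mean of the EX traces", {
  t <- seq(0, 999)
  v <- sin(2 * pi * 6 * t / 1000)
  expect_equal(compute_lfp(cbind(v, v, v)), v)
  expect_equal(compute_lfp(cbind(v, -v)), rep(0, length(v)))
  m <- matrix(rnorm(1000 * 100), ncol = 100)
  loop <- vapply(seq_len(nrow(m)), function(i) {
    acc <- 0
    for (j in seq_len(ncol(m))) acc <- acc + m[i, j]
    acc / ncol(m)
  }, numeric(1))                                  # naive loop oracle
  expect_equal(compute_lfp(m), loop)
  expect_error(compute_lfp(m[, 0, drop = FALSE]), "at least one")
})

test_that("Morlet transform localises tones and rejects bad frequencies", {
  dt <- 1
  t <- seq(0, 3999) * dt / 1000
  freqs <- c(seq(2, 30, 1), seq(32, 80, 2))
  spec <- morlet_transform(sin(2 * pi * 6 * t), freqs, dt)
  expect_equal(spec$frequency[which.max(colMeans(spec$amplitude))], 6)
  # two tones: ridges at both, matching an FFT peak oracle
  x <- sin(2 * pi * 6 * t) + 0.8 * sin(2 * pi * 45 * t)
  pw <- Mod(fft(x))[2:2000]
  fr <- (1:1999) / 4
  fft_peaks <- sort(fr[order(-pw)[1:2]])
  spec2 <- morlet_transform(x, freqs, dt)
  prof <- colMeans(spec2$amplitude)
  lo <- spec2$frequency[spec2$frequency < 20]
  hi <- spec2$frequency[spec2$frequency >= 20]
  expect_equal(lo[which.max(prof[spec2$frequency < 20])], fft_peaks[1],
               tolerance = 0.51)
  expect_equal(hi[which.max(prof[spec2$frequency >= 20])], fft_peaks[2],
               tolerance = 1.01)
  expect_true(all(morlet_transform(rep(0, 512), freqs, dt)$amplitude == 0))
  expect_error(morlet_transform(x, 600, dt), "Nyquist")
})

test_that("band amplitude: degenerate band, window mean, linear scaling", {
  dt <- 1
  t <- seq(0, 2999) * dt / 1000
  x <- sin(2 * pi * 6 * t)
  spec <- morlet_transform(x, 2:20, dt)
  one_bin <- band_mean_amplitude(spec, c(6, 6))
  expect_equal(one_bin$series, spec$amplitude[, spec$frequency == 6])
  expect_equal(one_bin$mean, mean(one_bin$series))
  # scalar equals time-mean of the series over the stated window
  b <- band_mean_amplitude(spec, c(4, 8), window = c(500, 2500))
  expect_equal(b$mean, mean(b$series[spec$time >= 500 & spec$time <= 2500]))
  # linearity in signal amplitude
  spec3 <- morlet_transform(3 * x, 2:20, dt)
  expect_equal(band_mean_amplitude(spec3, c(4, 8))$mean,
               3 * band_mean_amplitude(spec, c(4, 8))$mean,
               tolerance = 1e-10)
  expect_error(band_mean_amplitude(spec, c(25, 30)), "band")
})

test_that("theta phase: identical traces, analytic shift, continuity", {
  dt <- 1
  t <- seq(0, 2999) * dt / 1000
  f0 <- 6
  v1 <- sin(2 * pi * f0 * t)
  v2 <- sin(2 * pi * f0 * (t - 1 / (4 * f0)))   # quarter-period lag
  ph <- theta_phase_per_neuron(cbind(v1, v1, v2), dt = dt)
  expect_equal(ph[, 1], ph[, 2])
  mid <- 500:2500
  dphi <- (ph[mid, 1] - ph[mid, 3]) %% (2 * pi)
  expect_equal(mean(dphi), pi / 2, tolerance = 0.05)
  # continuity modulo wrap: steps are small except near 2*pi wraps
  steps <- diff(ph[mid, 1])
  expect_true(all(abs(steps) < 0.2 | abs(steps + 2 * pi) < 0.2))
  expect_error(theta_phase_per_neuron(cbind(v1[1:100]), dt = dt),
               "too short")
})

test_that("phase variation: zero iff synchronised, uniform limit, rotation", {
  n_t <- 50
  same <- matrix(rep(runif(n_t, 0, 2 * pi), 20), nrow = n_t)
  expect_equal(phase_variation(same)$mean, 0)
  # uniform phases over the circle: 1 - R -> 1 (Monte-Carlo, large n)
  set.seed(42)
  unif <- matrix(runif(n_t * 2000, 0, 2 * pi), nrow = n_t)
  expect_equal(phase_variation(unif)$mean, 1, tolerance = 0.05)
  # invariance under a common rotation
  base <- matrix(runif(n_t * 30, 0, 2 * pi), nrow = n_t)
  rot <- (base + 1.234) %% (2 * pi)
  expect_equal(phase_variation(base)$mean, phase_variation(rot)$mean,
               tolerance = 1e-12)
  expect_error(phase_variation(base[, 1, drop = FALSE]), "two neurons")
})

test_that("nested counting: constructed volleys, empty input, invariance", {
  dt <- 1
  t_ms <- seq(0, 3999) * dt
  lfp <- sin(2 * pi * 5 * t_ms / 1000)          # 5 Hz, 200 ms cycles
  k <- 4                                         # 4 volleys per cycle
  volley_times <- unlist(lapply(seq(0, 3800, by = 200), function(c0)
    c0 + 25 + (0:(k - 1)) * 40))
  spikes <- rep(volley_times, each = 30) + rep(runif(30, -1, 1),
                                               times = length(volley_times))
  nc <- count_nested_spikes(lfp, t_ms, spikes, window = c(400, 3600))
  expect_true(all(nc$counts == k))
  expect_equal(nc$mean, k)
  # no spikes: zero per cycle
  nc0 <- count_nested_spikes(lfp, t_ms, numeric(0), window = c(400, 3600))
  expect_true(all(nc0$counts == 0))
  # invariant to LFP amplitude scaling
  nc10 <- count_nested_spikes(10 * lfp, t_ms, spikes, window = c(400, 3600))
  expect_equal(nc10$counts, nc$counts)
  expect_error(count_nested_spikes(lfp, t_ms, spikes, window = c(0, 150)),
               "theta cycle|too short")
})

test_that("wavelet power grows monotonically with tone amplitude", {
  dt <- 1
  t <- seq(0, 1999) * dt / 1000
  freqs <- seq(2, 20, 1)
  pw <- vapply(c(0.5, 1, 2, 4), function(a) {
    sum(morlet_transform(a * sin(2 * pi * 6 * t), freqs, dt)$amplitude^2)
  }, numeric(1))
  expect_true(all(diff(pw) > 0))
})
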