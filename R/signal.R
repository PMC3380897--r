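#' Model local field potential
#'
#' The LFP of the model is the pointwise arithmetic mean of the excitatory
#' membrane potentials.
#'
#' @param ex_potentials time x neuron matrix of EX membrane potentials (mV),
#'   or a `tg_sim`
#' @return numeric LFP series (mV)
#' @export
compute_lfp <- function(ex_potentials) {
  if (inherits(ex_potentials, "tg_sim")) ex_potentials <- ex_potentials$v_ex
  m <- as.matrix(ex_potentials)
  if (ncol(m) < 1) stop("need at least one EX trace")
  rowMeans(m)
}

# analytic signal via the frequency-domain Hilbert transform
tg_hilbert <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Zero-phase band-pass filter
#'
#' Frequency-domain band-pass with raised-cosine (half-Hann) band edges.
#' The gain is exactly 1 in the passband, rolls off over `transition` Hz on
#' each side, and the filter is exactly zero-phase, so it introduces no
#' phase bias into downstream phase/amplitude estimates.  The mean is
#' removed before filtering.
#'
#' @param x signal
#' @param dt sampling interval (ms)
#' @param f_lo,f_hi passband edges (Hz)
#' @param transition transition-band width (Hz); default one quarter of the
#'   passband width
#' @return filtered signal, same length
#' @export
tg_bandpass <- function(x, dt, f_lo, f_hi, transition = NULL) {
  stopifnot(f_hi > f_lo, f_lo > 0)
  fs <- 1000 / dt
  if (f_hi >= fs / 2) stop("band edge at or above the Nyquist frequency")
  if (is.null(transition)) transition <- (f_hi - f_lo) / 4
  n <- length(x)
  x0 <- x - mean(x)
  freqs <- (seq_len(n) - 1) / n * fs
  freqs <- pmin(freqs, fs - freqs)  # fold: |f| on the full FFT axis
  gain <- numeric(n)
  pass <- freqs >= f_lo & freqs <= f_hi
  gain[pass] <- 1
  lo_edge <- freqs >= f_lo - transition & freqs < f_lo
  gain[lo_edge] <- 0.5 * (1 + cos(pi * (f_lo - freqs[lo_edge]) / transition))
  hi_edge <- freqs > f_hi & freqs <= f_hi + transition
  gain[hi_edge] <- 0.5 * (1 + cos(pi * (freqs[hi_edge] - f_hi) / transition))
  Re(fft(fft(x0) * gain, inverse = TRUE) / n)
}

#' Morlet wavelet transform
#'
#' Convolves the signal with scaled Morlet wavelets
#' \eqn{\psi(\eta) = \pi^{-1/4} e^{i\omega_0\eta} e^{-\eta^2/2}} (default
#' centre parameter \eqn{\omega_0 = 6} cycles), evaluated per frequency in
#' the Fourier domain.  Coefficients are normalised so that a pure tone of
#' amplitude A at an analysis frequency has modulus A at its ridge, i.e.
#' the amplitude spectrum is read directly in signal units.
#'
#' @param signal numeric series, or a `tg_sim` (its LFP is used)
#' @param frequencies analysis frequencies (Hz), all below Nyquist
#' @param dt sampling interval (ms); taken from the `tg_sim` when given one
#' @param omega0 Morlet centre parameter (cycles)
#' @return an object of class `tg_spectrogram` with fields `time` (ms),
#'   `frequency` (Hz), `coefficients` (time x frequency complex matrix) and
#'   `amplitude` (its modulus)
#' @examples
#' t <- seq(0, 2000, by = 1)
#' spec <- morlet_transform(sin(2 * pi * 6 * t / 1000), 2:20, dt = 1)
#' spec$frequency[which.max(colMeans(spec$amplitude))]
#' @export
morlet_transform <- function(signal, frequencies, dt = 1, omega0 = 6) {
  if (inherits(signal, "tg_sim")) {
    dt <- diff(signal$time[1:2])
    time <- signal$time
    signal <- signal$lfp
  } else {
    time <- (seq_along(signal) - 1) * dt
  }
  stopifnot(all(is.finite(signal)), all(frequencies > 0))
  fs <- 1000 / dt
  if (any(frequencies >= fs / 2))
    stop("analysis frequency at or above the Nyquist frequency")
  n <- length(signal)
  npad <- nextn(n)
  xhat <- fft(c(signal - mean(signal), numeric(npad - n)))
  w <- 2 * pi * (seq_len(npad) - 1) / npad * fs      # rad/s on the FFT axis
  pos <- w < pi * fs                                  # positive-frequency half
  coef <- matrix(0i, nrow = n, ncol = length(frequencies))
  for (j in seq_along(frequencies)) {
    s <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi * frequencies[j])  # scale (s)
    win <- numeric(npad)
    # factor 2: analytic-signal convention so a tone of amplitude A gives
    # ridge modulus A rather than A/2
    win[pos] <- 2 * exp(-0.5 * (s * w[pos] - omega0)^2)
    coef[, j] <- (fft(xhat * win, inverse = TRUE) / npad)[seq_len(n)]
  }
  structure(list(time = time, frequency = frequencies,
                 coefficients = coef, amplitude = abs(coef)),
            class = "tg_spectrogram")
}

#' Band-averaged wavelet amplitude
#'
#' Frequency-mean of the wavelet amplitude within a band, per time point,
#' plus its time-average over an analysis window.  The published theta and
#' gamma readouts are this statistic over 4-8 Hz and 30-70 Hz.
#'
#' @param spec a [morlet_transform()] result
#' @param band `c(f_lo, f_hi)` (Hz); must intersect the frequency grid
#' @param window `c(t0, t1)` (ms); defaults to the full time grid
#' @param power use squared modulus instead of modulus
#' @return an object of class `tg_band_amplitude` with fields `band`,
#'   `window`, `time`, `series` (band-mean amplitude per time point) and
#'   `mean` (its time-average over the window)
#' @export
band_mean_amplitude <- function(spec, band, window = NULL, power = FALSE) {
  stopifnot(inherits(spec, "tg_spectrogram"), length(band) == 2)
  sel <- spec$frequency >= band[1] & spec$frequency <= band[2]
  if (!any(sel)) stop("band does not intersect the frequency grid")
  a <- spec$amplitude[, sel, drop = FALSE]
  if (power) a <- a^2
  series <- rowMeans(a)
  if (is.null(window)) window <- range(spec$time)
  in_win <- spec$time >= window[1] & spec$time <= window[2]
  if (!any(in_win)) stop("empty analysis window")
  structure(list(band = band, window = window, time = spec$time,
                 series = series, mean = mean(series[in_win])),
            class = "tg_band_amplitude")
}

#' Theta-band instantaneous phase of each EX neuron
#'
#' Band-passes every EX membrane trace to the theta band and takes the
#' instantaneous phase of the analytic (Hilbert) signal, giving one phase
#' series per neuron on the common time grid.
#'
#' @param ex_potentials time x neuron matrix, or a `tg_sim`
#' @param dt sampling interval (ms); taken from the `tg_sim` when given one
#' @param band `c(f_lo, f_hi)` (Hz), default theta 4-8
#' @return time x neuron matrix of phases in `[0, 2*pi)`
#' @export
theta_phase_per_neuron <- function(ex_potentials, dt = 1, band = c(4, 8)) {
  if (inherits(ex_potentials, "tg_sim")) {
    dt <- diff(ex_potentials$time[1:2])
    ex_potentials <- ex_potentials$v_ex
  }
  m <- as.matrix(ex_potentials)
  min_len <- ceiling(3 * 1000 / band[1] / dt)   # a few cycles of the low edge
  if (nrow(m) < min_len)
    stop("traces too short for theta-phase extraction (need >= ",
         min_len, " samples)")
  phases <- apply(m, 2, function(v) {
    Arg(tg_hilbert(tg_bandpass(v, dt, band[1], band[2]))) %% (2 * pi)
  })
  phases
}

#' Across-neuron theta-phase variation
#'
#' Circular dispersion `1 - R` of the per-neuron theta phases at each time
#' point (R = resultant length across neurons), averaged over the analysis
#' window.  Zero iff all neurons share one phase at every time; the smaller
#' the value the more synchronised the theta phases.  `statistic =
#' "linear"` instead uses the across-neuron variance of the phase after
#' centring on the circular mean, as a sensitivity alternative.
#'
#' @param phases time x neuron phase matrix from [theta_phase_per_neuron()]
#' @param time time grid (ms) matching the rows; defaults to row index
#' @param window `c(t0, t1)` (ms)
#' @param statistic `"circular"` (default) or `"linear"`
#' @return an object of class `tg_phase_variation` with fields `series`
#'   (per-time dispersion) and `mean` (its window average)
#' @export
phase_variation <- function(phases, time = NULL, window = NULL,
                            statistic = c("circular", "linear")) {
  statistic <- match.arg(statistic)
  m <- as.matrix(phases)
  if (ncol(m) < 2) stop("need phases from at least two neurons")
  if (is.null(time)) time <- seq_len(nrow(m))
  z <- exp(1i * m)
  R <- Mod(rowMeans(z))
  series <- if (statistic == "circular") {
    1 - R
  } else {
    mu <- Arg(rowMeans(z))
    dev <- (m - mu + pi) %% (2 * pi) - pi
    apply(dev, 1, function(r) mean(r^2))
  }
  if (is.null(window)) window <- range(time)
  in_win <- time >= window[1] & time <= window[2]
  if (!any(in_win)) stop("empty analysis window")
  structure(list(time = time, series = series, mean = mean(series[in_win]),
                 statistic = statistic),
            class = "tg_phase_variation")
}

#' Count nested gamma events per theta cycle
#'
#' Theta cycles are delimited by consecutive wraps of the Hilbert phase of
#' the theta-band-filtered LFP.  Within the analysis window the pooled EX
#' spike train is binned into a population rate histogram (1 ms bins,
#' 3 ms boxcar smoothing) and gamma events are taken as local maxima above
#' a fraction of the window's peak rate with a minimum separation of one
#' high-end gamma period; the events falling inside each complete theta
#' cycle are counted.
#'
#' @param lfp LFP series, or a `tg_sim` (LFP and EX spikes taken from it)
#' @param time time grid (ms) matching `lfp`
#' @param ex_spikes pooled EX spike times (ms); ignored for a `tg_sim`
#' @param window analysis window `c(t0, t1)` (ms); defaults to the stimulus
#'   window for a `tg_sim`, otherwise the full grid
#' @param theta_band theta band for cycle extraction (Hz)
#' @param bin_ms histogram bin (ms)
#' @param smooth_ms boxcar width (ms)
#' @param threshold_frac event threshold as a fraction of the window peak
#'   rate
#' @param min_separation_ms minimum event separation (ms); one gamma period
#'   at the 100 Hz upper bound by default
#' @return an object of class `tg_nested_count` with fields `counts`
#'   (per complete cycle), `mean`, `cycles` (cycle boundary times) and
#'   `event_times`
#' @export
count_nested_spikes <- function(lfp, time = NULL, ex_spikes = NULL,
                                window = NULL, theta_band = c(4, 8),
                                bin_ms = 1, smooth_ms = 3,
                                threshold_frac = 0.2,
                                min_separation_ms = 10) {
  if (inherits(lfp, "tg_sim")) {
    sim <- lfp
    time <- sim$time
    ex_spikes <- sim$spikes$time[sim$spikes$population == "EX"]
    if (is.null(window))
      window <- c(sim$stimulus$onset,
                  min(sim$config$duration,
                      sim$stimulus$onset + sim$stimulus$duration))
    lfp <- sim$lfp
  }
  if (is.null(time)) time <- seq_along(lfp) - 1
  if (is.null(window)) window <- range(time)
  dt <- diff(time[1:2])

  phase <- Arg(tg_hilbert(tg_bandpass(lfp, dt, theta_band[1],
                                      theta_band[2]))) %% (2 * pi)
  wraps <- which(diff(phase) < -pi)          # 2*pi -> 0 crossings
  wrap_t <- time[wraps]
  wrap_t <- wrap_t[wrap_t >= window[1] & wrap_t <= window[2]]
  if (length(wrap_t) < 2)
    stop("no complete theta cycle inside the analysis window")

  # population rate histogram and gamma-event extraction
  edges <- seq(window[1], window[2], by = bin_ms)
  if (length(edges) < 4) stop("analysis window too short")
  sp <- ex_spikes[ex_spikes >= window[1] & ex_spikes <= window[2]]
  counts_hist <- tabulate(findInterval(sp, edges, rightmost.closed = TRUE),
                          nbins = length(edges) - 1)
  k <- max(1L, round(smooth_ms / bin_ms))
  kern <- rep(1 / k, k)
  sm <- stats::filter(counts_hist, kern, sides = 2)
  sm[is.na(sm)] <- 0
  sm <- as.numeric(sm)
  centers <- edges[-length(edges)] + bin_ms / 2

  thr <- threshold_frac * max(sm)
  events <- numeric(0)
  if (max(sm) > 0) {
    is_peak <- which(sm >= thr &
                       sm >= c(-Inf, sm[-length(sm)]) &
                       sm > c(sm[-1], -Inf))
    # enforce minimum separation, keeping the larger peak
    if (length(is_peak)) {
      ord <- is_peak[order(sm[is_peak], decreasing = TRUE)]
      keep <- logical(0)
      sel <- numeric(0)
      for (pk in ord) {
        if (!length(sel) || all(abs(centers[pk] - sel) >= min_separation_ms))
          sel <- c(sel, centers[pk])
      }
      events <- sort(sel)
    }
  }

  n_cyc <- length(wrap_t) - 1
  counts <- integer(n_cyc)
  for (i in seq_len(n_cyc))
    counts[i] <- sum(events >= wrap_t[i] & events < wrap_t[i + 1])
  structure(list(counts = counts, mean = mean(counts),
                 cycles = wrap_t, event_times = events, window = window),
            class = "tg_nested_count")
}

#' Peak frequency of the gamma band
#'
#' Frequency of maximal time-averaged wavelet amplitude within a band over
#' an analysis window.
#'
#' @param spec a [morlet_transform()] result
#' @param band search band (Hz)
#' @param window `c(t0, t1)` (ms)
#' @return peak frequency (Hz)
#' @export
gamma_peak_frequency <- function(spec, band = c(20, 80), window = NULL) {
  stopifnot(inherits(spec, "tg_spectrogram"))
  if (is.null(window)) window <- range(spec$time)
  in_win <- spec$time >= window[1] & spec$time <= window[2]
  sel <- which(spec$frequency >= band[1] & spec$frequency <= band[2])
  if (!length(sel) || !any(in_win)) stop("empty band or window")
  prof <- colMeans(spec$amplitude[in_win, sel, drop = FALSE])
  spec$frequency[sel[which.max(prof)]]
}
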