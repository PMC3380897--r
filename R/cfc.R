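#' Filter-bank specification for phase-amplitude coupling
#'
#' Default banks follow the published procedure: phase bands centred at
#' 2-20 Hz in 1 Hz steps with a 2 Hz bandwidth, amplitude bands centred at
#' 30-70 Hz in 2 Hz steps with a 4 Hz bandwidth.
#'
#' The amplitude-bank filters must let through the spectral sidebands that
#' carry the phase-amplitude modulation (a gamma carrier amplitude-modulated
#' at theta frequency f has sidebands f Hz away from the carrier), so their
#' transition skirts default to 8 Hz per side: the passband is the printed
#' 4 Hz, but modulation at frequencies up to ~10 Hz still reaches the
#' envelope with attenuated gain, as with the shallow skirts of a low-order
#' IIR filter.  The coupling index is amplitude-scale-free, so skirt
#' attenuation does not bias it.  Phase-bank skirts are kept narrow (1 Hz)
#' to preserve frequency resolution of the phase estimate.
#'
#' @param phase_centers centre frequencies (Hz) of the phase bank
#' @param phase_bandwidth full passband width (Hz) of each phase band
#' @param amp_centers centre frequencies (Hz) of the amplitude bank
#' @param amp_bandwidth full passband width (Hz) of each amplitude band
#' @param phase_transition,amp_transition transition-band width (Hz) per
#'   side of the zero-phase filters
#' @return an object of class `tg_filter_bank`
#' @export
filter_bank_spec <- function(phase_centers = 2:20, phase_bandwidth = 2,
                             amp_centers = seq(30, 70, by = 2),
                             amp_bandwidth = 4,
                             phase_transition = 1, amp_transition = 8) {
  stopifnot(phase_bandwidth > 0, amp_bandwidth > 0,
            phase_transition > 0, amp_transition > 0,
            all(phase_centers - phase_bandwidth / 2 > 0))
  structure(list(phase_centers = phase_centers,
                 phase_bandwidth = phase_bandwidth,
                 amp_centers = amp_centers,
                 amp_bandwidth = amp_bandwidth,
                 phase_transition = phase_transition,
                 amp_transition = amp_transition),
            class = "tg_filter_bank")
}

#' Band-passed phase and amplitude sets
#'
#' Step 1-2 of the coupling procedure: band-pass the raw signal through the
#' phase and amplitude banks (zero-phase filters, see [tg_bandpass()]) and
#' apply the Hilbert transform, keeping the instantaneous phase for the
#' phase bank and the amplitude envelope for the amplitude bank.
#'
#' @param signal raw series (e.g. an LFP)
#' @param dt sampling interval (ms)
#' @param bank a [filter_bank_spec()]
#' @return list with `phase` (time x phase-band matrix, radians in
#'   `[0, 2*pi)`) and `amplitude` (time x amplitude-band envelope matrix)
#' @export
bandpass_pair <- function(signal, dt, bank = filter_bank_spec()) {
  stopifnot(inherits(bank, "tg_filter_bank"))
  fs <- 1000 / dt
  if (max(bank$amp_centers) + bank$amp_bandwidth / 2 >= fs / 2)
    stop("amplitude band at or above the Nyquist frequency")
  ph <- vapply(bank$phase_centers, function(f0) {
    b <- tg_bandpass(signal, dt, f0 - bank$phase_bandwidth / 2,
                     f0 + bank$phase_bandwidth / 2,
                     transition = bank$phase_transition)
    Arg(tg_hilbert(b)) %% (2 * pi)
  }, numeric(length(signal)))
  am <- vapply(bank$amp_centers, function(f0) {
    b <- tg_bandpass(signal, dt, f0 - bank$amp_bandwidth / 2,
                     f0 + bank$amp_bandwidth / 2,
                     transition = bank$amp_transition)
    Mod(tg_hilbert(b))
  }, numeric(length(signal)))
  list(phase = ph, amplitude = am)
}

#' Phase-binned amplitude distribution
#'
#' Step 3-4 of the coupling procedure: bin the phase series into `n_bins`
#' equal intervals of `[0, 2*pi)`, average the amplitude within each bin,
#' and normalise the bin means to a distribution-like function P.
#'
#' @param phase phase series (radians)
#' @param amplitude amplitude series, same length
#' @param n_bins number of phase bins (published value 18)
#' @return an object of class `tg_amplitude_distribution` with fields
#'   `breaks`, `mean_amplitude` and `p` (normalised distribution)
#' @export
amplitude_distribution <- function(phase, amplitude, n_bins = 18) {
  stopifnot(length(phase) == length(amplitude), n_bins >= 2)
  bin <- pmin(floor((phase %% (2 * pi)) / (2 * pi) * n_bins) + 1, n_bins)
  if (length(unique(bin)) < n_bins)
    stop("empty phase bin: analysis window too short for this phase band")
  mean_amp <- vapply(seq_len(n_bins),
                     function(b) mean(amplitude[bin == b]), numeric(1))
  total <- sum(mean_amp)
  if (total <= 0) stop("amplitude series sums to zero")
  structure(list(breaks = seq(0, 2 * pi, length.out = n_bins + 1),
                 mean_amplitude = mean_amp, p = mean_amp / total),
            class = "tg_amplitude_distribution")
}

#' KL-distance coupling coherence of one amplitude distribution
#'
#' The Kullback-Leibler distance of the phase-binned amplitude distribution
#' P from the uniform distribution U, normalised by `log(N)` so the result
#' lies in `[0, 1]`: 0 for a uniform P (no phase-amplitude dependence), 1
#' when all amplitude concentrates in a single phase bin.  Natural
#' logarithms throughout (any consistent base cancels); `0 * log(0)` is
#' taken as 0.
#'
#' @param dist a [amplitude_distribution()] result, or a bare probability
#'   vector
#' @return coherence scalar in `[0, 1]`
#' @export
kl_coherence <- function(dist) {
  p <- if (inherits(dist, "tg_amplitude_distribution")) dist$p else dist
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-8)
  n <- length(p)
  nz <- p > 0
  kl <- sum(p[nz] * log(p[nz] * n))
  kl / log(n)
}

#' Phase-amplitude coupling comodulogram
#'
#' Computes the KL coupling coherence for every (phase band, amplitude
#' band) pair of the filter bank over an analysis window, plus the scalar
#' summary.  The published scalar is the arithmetic mean over all pairs of
#' the two banks; `theta_rows_only = TRUE` restricts the average to phase
#' bands centred in 4-8 Hz as a sensitivity alternative.
#'
#' @param signal raw series, or a `tg_sim` (its LFP is used, and `window`
#'   defaults to the stimulus window)
#' @param dt sampling interval (ms); taken from the `tg_sim` when given one
#' @param bank a [filter_bank_spec()]
#' @param window analysis window `c(t0, t1)` (ms); the filters are applied
#'   to the full signal and the window selects samples for binning.  Should
#'   cover several cycles of the slowest phase band.
#' @param n_bins phase bins (published value 18)
#' @param theta_rows_only average only phase rows centred in 4-8 Hz
#' @param on_empty what to do when a phase bin is empty (window too short
#'   for that phase band): `"error"` (default) or `"na"` (drop the row
#'   from the average with a warning)
#' @param pair optional precomputed [bandpass_pair()] result to reuse
#'   across windows
#' @return an object of class `tg_cfc` with fields `matrix` (phase x
#'   amplitude coherence), `mean` (scalar), `bank`, `window`, `n_bins`
#' @export
cfc_matrix <- function(signal, dt = 1, bank = filter_bank_spec(),
                       window = NULL, n_bins = 18, theta_rows_only = FALSE,
                       on_empty = c("error", "na"), pair = NULL) {
  on_empty <- match.arg(on_empty)
  if (inherits(signal, "tg_sim")) {
    sim <- signal
    dt <- diff(sim$time[1:2])
    if (is.null(window))
      window <- c(sim$stimulus$onset,
                  min(sim$config$duration,
                      sim$stimulus$onset + sim$stimulus$duration))
    time <- sim$time
    signal <- sim$lfp
  } else {
    time <- (seq_along(signal) - 1) * dt
  }
  if (is.null(window)) window <- range(time)
  if (is.null(pair)) pair <- bandpass_pair(signal, dt, bank)
  sel <- which(time >= window[1] & time <= window[2])
  if (length(sel) < 10 * n_bins)
    stop("analysis window too short for stable phase binning")

  np <- length(bank$phase_centers)
  na <- length(bank$amp_centers)
  m <- matrix(NA_real_, np, na,
              dimnames = list(phase_hz = bank$phase_centers,
                              amp_hz = bank$amp_centers))
  for (i in seq_len(np)) {
    ph <- pair$phase[sel, i]
    bin <- pmin(floor(ph / (2 * pi) * n_bins) + 1, n_bins)
    if (length(unique(bin)) < n_bins) {
      if (on_empty == "error")
        stop("empty phase bin at ", bank$phase_centers[i],
             " Hz: widen the analysis window")
      warning("empty phase bin at ", bank$phase_centers[i],
              " Hz: row dropped", call. = FALSE)
      next
    }
    for (j in seq_len(na)) {
      amp <- pair$amplitude[sel, j]
      mean_amp <- vapply(seq_len(n_bins),
                         function(b) mean(amp[bin == b]), numeric(1))
      m[i, j] <- kl_coherence(mean_amp / sum(mean_amp))
    }
  }
  rows <- if (theta_rows_only) {
    bank$phase_centers >= 4 & bank$phase_centers <= 8
  } else rep(TRUE, np)
  structure(list(matrix = m, mean = mean(m[rows, , drop = FALSE],
                                         na.rm = TRUE),
                 bank = bank, window = window, n_bins = n_bins,
                 theta_rows_only = theta_rows_only),
            class = "tg_cfc")
}

#' Pre- versus during-stimulus coupling
#'
#' Convenience wrapper computing the coupling comodulogram separately for
#' the epoch before stimulus onset and the epoch while the stimulus is on,
#' reusing one filter pass over the whole recording.
#'
#' @param sim a `tg_sim`
#' @param bank a [filter_bank_spec()]
#' @param n_bins phase bins
#' @param ... passed to [cfc_matrix()]
#' @return list with elements `pre` and `during`, each a `tg_cfc`
#' @export
cfc_epochs <- function(sim, bank = filter_bank_spec(), n_bins = 18,
                       on_empty = "na", ...) {
  stopifnot(inherits(sim, "tg_sim"))
  dt <- diff(sim$time[1:2])
  pair <- bandpass_pair(sim$lfp, dt, bank)
  on <- sim$stimulus$onset
  off <- min(sim$config$duration, on + sim$stimulus$duration)
  pre <- suppressWarnings(
    cfc_matrix(sim$lfp, dt, bank, window = c(sim$config$warmup, on),
               n_bins = n_bins, on_empty = on_empty, pair = pair, ...))
  during <- suppressWarnings(
    cfc_matrix(sim$lfp, dt, bank, window = c(on, off),
               n_bins = n_bins, on_empty = on_empty, pair = pair, ...))
  list(pre = pre, during = during)
}
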