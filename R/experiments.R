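# Default Morlet analysis grid: 1 Hz resolution through the theta range,
# 2 Hz above it, spanning the full gamma search band.
tg_analysis_frequencies <- function() c(seq(2, 30, by = 1), seq(32, 90, by = 2))

#' Standard readouts of one simulation
#'
#' Computes the per-condition readouts used by all experiment protocols:
#' theta and gamma band amplitudes, the coupling coherence scalar,
#' theta-phase variation, firing rates, the nested-event count and the
#' gamma peak frequency, all over the stimulus window unless overridden.
#'
#' @param sim a `tg_sim`
#' @param readouts character vector choosing which readouts to compute
#'   (computing fewer is faster); any of `"theta_amp"`, `"gamma_amp"`,
#'   `"cfc"`, `"phase_variation"`, `"ex_rate"`, `"downstream_rate"`,
#'   `"nested_count"`, `"gamma_peak"`
#' @param window analysis window (ms); defaults to the stimulus window
#' @param theta_band,gamma_band analysis bands (Hz)
#' @return one-row data.frame with the requested readouts (others `NA`)
#' @export
analyze_sim <- function(sim,
                        readouts = c("theta_amp", "gamma_amp", "cfc",
                                     "cfc_theta", "phase_variation",
                                     "ex_rate", "downstream_rate"),
                        window = NULL, theta_band = c(4, 8),
                        gamma_band = c(30, 70)) {
  stopifnot(inherits(sim, "tg_sim"))
  if (is.null(window))
    window <- c(sim$stimulus$onset,
                min(sim$config$duration,
                    sim$stimulus$onset + sim$stimulus$duration))
  out <- data.frame(theta_amp = NA_real_, gamma_amp = NA_real_,
                    cfc = NA_real_, cfc_theta = NA_real_,
                    phase_variation = NA_real_,
                    ex_rate = NA_real_, downstream_rate = NA_real_,
                    nested_count = NA_real_, gamma_peak = NA_real_)
  need_spec <- any(c("theta_amp", "gamma_amp", "gamma_peak") %in% readouts)
  if (need_spec) {
    spec <- morlet_transform(sim, tg_analysis_frequencies())
    if ("theta_amp" %in% readouts)
      out$theta_amp <- band_mean_amplitude(spec, theta_band, window)$mean
    if ("gamma_amp" %in% readouts)
      out$gamma_amp <- band_mean_amplitude(spec, gamma_band, window)$mean
    if ("gamma_peak" %in% readouts)
      out$gamma_peak <- gamma_peak_frequency(spec, c(20, 80), window)
  }
  if (any(c("cfc", "cfc_theta") %in% readouts)) {
    cm <- suppressWarnings(cfc_matrix(sim, window = window,
                                      on_empty = "na"))
    out$cfc <- cm$mean
    rows <- as.numeric(rownames(cm$matrix))
    out$cfc_theta <- mean(cm$matrix[rows >= 4 & rows <= 8, , drop = FALSE],
                          na.rm = TRUE)
  }
  if ("phase_variation" %in% readouts) {
    ph <- theta_phase_per_neuron(sim, band = theta_band)
    out$phase_variation <- phase_variation(ph, time = sim$time,
                                           window = window)$mean
  }
  if ("ex_rate" %in% readouts)
    out$ex_rate <- population_rate(sim, "EX", window)
  if ("downstream_rate" %in% readouts)
    out$downstream_rate <- downstream_response(sim, window = window)$rate
  if ("nested_count" %in% readouts) {
    nc <- try(count_nested_spikes(sim, window = window), silent = TRUE)
    out$nested_count <- if (inherits(nc, "try-error")) NA_real_ else nc$mean
  }
  out
}

#' Parameter sweep
#'
#' Runs the network once per (grid value x seed), overriding one
#' configuration parameter, and collects the standard readouts.  Parameter
#' names are the 12 coupling conductances, `"stimulus"` (pulse amplitude,
#' nA) or a background current (`"bg_ex"`, `"bg_inf"`, `"bg_ins"`).
#' Simulation failures at a grid point are recorded as `NA` rows, not
#' raised.
#'
#' @param param parameter name
#' @param values numeric grid
#' @param base a [network_config()] used as the base condition
#' @param stimulus a [stimulus_protocol()]
#' @param seeds integer vector of replicate seeds
#' @param readouts passed to [analyze_sim()]
#' @return data.frame of class `tg_experiment_table`, one row per
#'   (value x seed)
#' @export
run_sweep <- function(param, values, base = network_config(),
                      stimulus = stimulus_protocol(duration = 1500),
                      seeds = 1:3,
                      readouts = c("theta_amp", "gamma_amp", "cfc",
                                   "cfc_theta", "phase_variation",
                                   "ex_rate", "downstream_rate")) {
  rows <- list()
  for (v in values) for (s in seeds) {
    cfg <- .apply_override(base, param, v)
    cfg$seed <- as.integer(s)
    stim <- stimulus
    if (param == "stimulus") stim$amplitude <- v
    row <- tryCatch({
      sim <- run_simulation(build_network(cfg), stim)
      analyze_sim(sim, readouts)
    }, error = function(e) {
      warning("grid point ", param, " = ", v, ", seed ", s, " failed: ",
              conditionMessage(e), call. = FALSE)
      analyze_frame_na()
    })
    rows[[length(rows) + 1]] <- cbind(data.frame(param = param, value = v,
                                                 seed = s), row)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("tg_experiment_table", class(out))
  out
}

.apply_override <- function(config, param, value) {
  if (param %in% names(config$conductances)) {
    config$conductances[[param]] <- value
    validate_config(config)
  } else if (param == "stimulus") {
    # handled by the caller on the protocol object
  } else if (param %in% c("bg_ex", "bg_inf", "bg_ins")) {
    key <- sub("bg_", "", param)
    config$background[[key]] <- value
  } else stop("unknown sweep parameter: ", param)
  config
}

analyze_frame_na <- function() {
  data.frame(theta_amp = NA_real_, gamma_amp = NA_real_, cfc = NA_real_,
             cfc_theta = NA_real_, phase_variation = NA_real_,
             ex_rate = NA_real_, downstream_rate = NA_real_,
             nested_count = NA_real_, gamma_peak = NA_real_)
}

#' Seed-averaged sweep curve
#'
#' @param table a [run_sweep()] result
#' @param readout readout column name
#' @return data.frame with `value` and the seed-mean of the readout
#' @export
sweep_curve <- function(table, readout) {
  agg <- stats::aggregate(table[[readout]],
                          by = list(value = table$value),
                          FUN = mean, na.rm = TRUE)
  names(agg)[2] <- readout
  agg[order(agg$value), ]
}

#' Learning-stage scenarios
#'
#' `run_learning_scenario_it()` reproduces the cortical (IT-like) scenario:
#' four stages that coordinately increase the EX-recurrent and EX-to-INs
#' NMDA conductances together with the slow-GABA INs-to-EX conductance, so
#' that theta amplitude and theta-gamma coupling grow together.
#' `run_learning_scenario_hippocampus()` reproduces the hippocampal-like
#' scenario: four stages increasing the fast-GABA INf-to-EX, INf-recurrent
#' and INs-to-INf conductances together, raising the coupling while
#' leaving theta amplitude roughly unchanged.
#'
#' @param stages list of named conductance-override vectors, one per stage;
#'   defaults to the published stage values
#' @param base base [network_config()]
#' @param stimulus a [stimulus_protocol()]
#' @param seeds replicate seeds averaged per stage
#' @param readouts passed to [analyze_sim()]
#' @return data.frame of class `tg_experiment_table`, one row per
#'   (stage x seed)
#' @export
run_learning_scenario_it <- function(stages = it_scenario_stages(),
                                     base = network_config(),
                                     stimulus = stimulus_protocol(duration = 1500),
                                     seeds = 1:3,
                                     readouts = c("theta_amp", "cfc",
                                                  "cfc_theta",
                                                  "phase_variation",
                                                  "downstream_rate")) {
  run_stages(stages, base, stimulus, seeds, readouts)
}

#' @rdname run_learning_scenario_it
#' @export
run_learning_scenario_hippocampus <- function(stages = hippocampus_scenario_stages(),
                                              base = network_config(),
                                              stimulus = stimulus_protocol(duration = 1500),
                                              seeds = 1:3,
                                              readouts = c("theta_amp", "cfc",
                                                           "cfc_theta",
                                                           "phase_variation",
                                                           "downstream_rate")) {
  run_stages(stages, base, stimulus, seeds, readouts)
}

run_stages <- function(stages, base, stimulus, seeds, readouts) {
  rows <- list()
  for (k in seq_along(stages)) for (s in seeds) {
    cfg <- base
    ov <- stages[[k]]
    if (length(ov)) {
      bad <- setdiff(names(ov), names(cfg$conductances))
      if (length(bad)) stop("unknown override(s): ", paste(bad, collapse = ", "))
      cfg$conductances[names(ov)] <- ov
    }
    cfg$seed <- as.integer(s)
    sim <- run_simulation(build_network(cfg), stimulus)
    rows[[length(rows) + 1]] <- cbind(data.frame(stage = k, seed = s),
                                      analyze_sim(sim, readouts))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("tg_experiment_table", class(out))
  out
}

#' Published stage values of the learning scenarios
#'
#' @return list of named conductance-override vectors, one per stage
#' @export
it_scenario_stages <- function() {
  list(c(g_NMee = 0.0001,  g_NMes = 0.001,  g_GAse = 0.05),
       c(g_NMee = 0.00025, g_NMes = 0.0025, g_GAse = 0.06),
       c(g_NMee = 0.00035, g_NMes = 0.004,  g_GAse = 0.07),
       c(g_NMee = 0.00045, g_NMes = 0.005,  g_GAse = 0.08))
}

#' @rdname it_scenario_stages
#' @export
hippocampus_scenario_stages <- function() {
  list(c(g_GAfe = 0.007, g_GAff = 0.03, g_GAsf = 0.02),
       c(g_GAfe = 0.01,  g_GAff = 0.05, g_GAsf = 0.02),
       c(g_GAfe = 0.015, g_GAff = 0.06, g_GAsf = 0.035),
       c(g_GAfe = 0.02,  g_GAff = 0.07, g_GAsf = 0.04))
}

#' Stimulus-strength capacity sweep
#'
#' Sweeps the stimulus amplitude over a grid (published range 0.5-1.5 nA),
#' locates the amplitude maximising the seed-averaged theta amplitude, and
#' reports at that operating point the nested-subcycle count, the gamma
#' peak frequency and the theta-phase variation.  The theta-amplitude
#' curve is bell-shaped in the published regime, so the argmax is an
#' interior grid point.
#'
#' @param stim_grid stimulus amplitudes (nA)
#' @param base base [network_config()] (conductance/background variants
#'   select the low- versus high-gamma regime)
#' @param seeds replicate seeds
#' @param stimulus_duration pulse length (ms); the analysis window is the
#'   pulse window
#' @param onset pulse onset (ms)
#' @param smooth half-width (grid points) of the boxcar applied to the
#'   theta curve before locating the argmax
#' @return list with `table` (per grid x seed readouts), `curve`
#'   (seed-averaged theta curve), `critical_stimulus`, `argmax_interior`
#'   (logical), `nested_count`, `gamma_peak`, `phase_variation_curve`,
#'   `phase_variation_argmin`
#' @export
capacity_sweep <- function(stim_grid = seq(0.5, 1.5, length.out = 21),
                           base = network_config(), seeds = 1:10,
                           stimulus_duration = 1500, onset = NULL,
                           smooth = 1) {
  if (is.null(onset)) onset <- base$warmup
  base$duration <- onset + stimulus_duration
  stim <- stimulus_protocol(onset = onset, duration = stimulus_duration)
  tab <- run_sweep("stimulus", stim_grid, base, stim, seeds,
                   readouts = c("theta_amp", "phase_variation",
                                "nested_count", "gamma_peak"))
  curve <- sweep_curve(tab, "theta_amp")
  th <- curve$theta_amp
  if (smooth > 0) {
    k <- 2 * smooth + 1
    sm <- stats::filter(th, rep(1 / k, k), sides = 2)
    th <- ifelse(is.na(sm), th, as.numeric(sm))
  }
  i_max <- which.max(th)
  pv_curve <- sweep_curve(tab, "phase_variation")
  at_max <- tab[tab$value == curve$value[i_max], ]
  list(table = tab, curve = curve,
       critical_stimulus = curve$value[i_max],
       argmax_interior = i_max > 1 && i_max < nrow(curve),
       nested_count = mean(at_max$nested_count, na.rm = TRUE),
       gamma_peak = mean(at_max$gamma_peak, na.rm = TRUE),
       phase_variation_curve = pv_curve,
       phase_variation_argmin = pv_curve$value[which.min(pv_curve$phase_variation)])
}

#' Configuration variants for the capacity experiment
#'
#' Named conductance/background variants, all within the printed ranges,
#' that move the gamma spectral peak of the network between the low
#' (20-50 Hz) and high (>50 Hz) gamma regimes for the capacity sweep.
#'
#' @param regime `"low_gamma"` or `"high_gamma"`
#' @return a [network_config()]
#' @export
capacity_variant <- function(regime = c("high_gamma", "low_gamma")) {
  regime <- match.arg(regime)
  switch(regime,
    high_gamma = network_config(conductances = c(g_GAfe = 0.05,
                                                 g_GAse = 0.04)),
    low_gamma = network_config(conductances = c(g_GAfe = 0.05),
                               background = list(inf = 0.75)))
}

#' Synthetic phase-amplitude-coupled signal specification
#'
#' Describes the test fixture emulating an LFP whose theta phase modulates
#' a gamma envelope:
#' \deqn{s(t) = A_\theta \sin(2\pi f_\theta t) +
#'   A_\gamma (1 + m \sin(2\pi f_\theta t)) \sin(2\pi f_\gamma t) +
#'   \epsilon(t)}
#' with Gaussian noise of standard deviation `noise_sd`.
#'
#' @param theta_freq theta carrier (Hz)
#' @param gamma_freq gamma carrier (Hz); must exceed `theta_freq`
#' @param m modulation depth in `[0, 1]`
#' @param theta_amp,gamma_amp carrier amplitudes
#' @param noise_sd additive Gaussian noise SD
#' @param duration signal length (ms)
#' @param dt sampling interval (ms)
#' @param seed RNG seed for the noise
#' @return an object of class `tg_coupled_signal_spec`
#' @export
coupled_signal_spec <- function(theta_freq = 6, gamma_freq = 45, m = 0.5,
                                theta_amp = 1, gamma_amp = 0.5,
                                noise_sd = 0.1, duration = 10000, dt = 1,
                                seed = 1L) {
  stopifnot(m >= 0, m <= 1, theta_freq > 0, gamma_freq > theta_freq,
            duration > 0, dt > 0, noise_sd >= 0)
  structure(list(theta_freq = theta_freq, gamma_freq = gamma_freq, m = m,
                 theta_amp = theta_amp, gamma_amp = gamma_amp,
                 noise_sd = noise_sd, duration = duration, dt = dt,
                 seed = as.integer(seed)),
            class = "tg_coupled_signal_spec")
}

#' Generate a synthetic coupled signal
#'
#' @param spec a [coupled_signal_spec()]
#' @return list with `time` (ms), `signal`, and the `spec`
#' @examples
#' sig <- generate_coupled_signal(coupled_signal_spec(m = 1, noise_sd = 0))
#' @export
generate_coupled_signal <- function(spec = coupled_signal_spec()) {
  stopifnot(inherits(spec, "tg_coupled_signal_spec"))
  t_s <- seq(0, spec$duration - spec$dt, by = spec$dt) / 1000
  theta <- sin(2 * pi * spec$theta_freq * t_s)
  carrier <- sin(2 * pi * spec$gamma_freq * t_s)
  noise <- with_substream(spec$seed, "fixture_noise",
                          rnorm(length(t_s), sd = spec$noise_sd))
  sig <- spec$theta_amp * theta +
    spec$gamma_amp * (1 + spec$m * theta) * carrier + noise
  list(time = t_s * 1000, signal = sig, spec = spec)
}
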