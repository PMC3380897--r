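# Published conductance matrix (uS) and printed plausible ranges.  The twelve
# couplings are named g_<receptor><source><target> with receptor AM (AMPA),
# NM (NMDA) or GA (GABA-A), and populations e (EX), f (INf), s (INs).
.tg_conductance_defaults <- c(
  g_AMee = 0.03,   g_AMef = 0.03,   g_AMes = 0.001,
  g_NMee = 0.001,  g_NMef = 0.001,  g_NMes = 0.0001,
  g_GAff = 0.05,   g_GAfe = 0.015,  g_GAfs = 0.00,
  g_GAss = 0.08,   g_GAse = 0.06,   g_GAsf = 0.04)

# Printed ranges.  Note the g_GAss row of the published table is internally
# inconsistent (default 0.08 outside the printed 0.007-0.05); range checks
# are therefore advisory (warnings), never errors.
.tg_conductance_ranges <- list(
  g_AMee = c(0.01, 0.05),    g_AMef = c(0.02, 0.08),  g_AMes = c(0.0001, 0.01),
  g_NMee = c(0.0001, 0.008), g_NMef = c(0.0001, 0.005), g_NMes = c(0.0001, 0.0005),
  g_GAff = c(0.01, 0.08),    g_GAfe = c(0.005, 0.05), g_GAfs = c(0.0, 0.05),
  g_GAss = c(0.007, 0.05),   g_GAse = c(0.02, 0.1),   g_GAsf = c(0.02, 0.08))

.tg_stimulus_range <- c(0.5, 1.5)

#' Network configuration
#'
#' Assembles everything a simulation run needs: population sizes, the full
#' 12-coupling conductance matrix, connectivity mode, background currents,
#' membrane and kinetic constants, and integration settings.  Defaults are
#' the published parameter set for the 100/50/50 all-to-all network.
#'
#' Conductance interpretation: with `conductance_scaling = "per_projection"`
#' (the default) each coupling value `g` is the maximal total conductance a
#' single target neuron receives from the whole source population, realised
#' as a per-synapse weight `g / n_source`.  With `"per_synapse"` the value
#' is used per synapse unscaled.  See the methods vignette for why the
#' projection-total reading is the one that places the rhythms in the
#' theta and gamma bands.
#'
#' @param n_ex,n_inf,n_ins population sizes (excitatory, fast inhibitory,
#'   slow inhibitory)
#' @param conductances named numeric vector; any subset of the 12 couplings,
#'   merged over the published defaults
#' @param connectivity `"all_to_all"` or `"bernoulli"` (each directed pair
#'   connected independently with probability `p`); autapses are always
#'   excluded
#' @param p connection probability for `"bernoulli"`
#' @param background list with per-population mean background currents (nA)
#'   `ex`, `inf`, `ins` and `ex_heterogeneity`, the half-width fraction of
#'   the uniform jitter applied to the EX backgrounds (one draw per neuron,
#'   held fixed for the whole run)
#' @param neuron_ex,neuron_in [neuron_params()] for the excitatory and the
#'   (shared) inhibitory populations
#' @param kinetics kinetics table as from [default_kinetics_table()]
#' @param conductance_scaling `"per_projection"` or `"per_synapse"`
#' @param mg_conc magnesium concentration (mM) for the NMDA voltage block
#' @param synaptic_delay synaptic transmission delay (ms): a scalar shared
#'   by all classes or a named vector over `ampa`, `nmda`, `gaba_fast`,
#'   `gaba_slow`.  The slow-GABA delay is the one that stabilises
#'   full-volley synchrony of the slow interneurons and hence the theta
#'   clock (see the methods vignette)
#' @param dt integration step (ms)
#' @param duration simulated time (ms)
#' @param warmup initial transient discarded by the analysis helpers (ms)
#' @param record_dt sampling interval of recorded membrane traces (ms)
#' @param seed integer seed controlling connectivity, background
#'   heterogeneity and initial conditions
#' @return an object of class `tg_config`
#' @examples
#' cfg <- network_config(duration = 1500, seed = 1)
#' cfg$conductances[["g_GAse"]]
#' @export
network_config <- function(n_ex = 100, n_inf = 50, n_ins = 50,
                           conductances = NULL,
                           connectivity = c("all_to_all", "bernoulli"),
                           p = 1,
                           background = list(ex = 0.7, inf = 0.85, ins = 0.6,
                                             ex_heterogeneity = 0.1),
                           neuron_ex = neuron_params(),
                           neuron_in = neuron_params(capacitance = 0.2,
                                                     leak_conductance = 0.02,
                                                     refractory_period = 1),
                           kinetics = default_kinetics_table(),
                           conductance_scaling = c("per_projection",
                                                   "per_synapse"),
                           mg_conc = 1,
                           synaptic_delay = 4,
                           dt = 0.05, duration = 2000, warmup = 500,
                           record_dt = 1, seed = 1L) {
  connectivity <- match.arg(connectivity)
  conductance_scaling <- match.arg(conductance_scaling)
  stopifnot(n_ex > 0, n_inf > 0, n_ins > 0, dt > 0, duration > 0,
            record_dt >= dt, warmup >= 0)
  if (connectivity == "bernoulli" && (p <= 0 || p > 1))
    stop("connection probability p must lie in (0, 1]")
  g <- .tg_conductance_defaults
  if (!is.null(conductances)) {
    bad <- setdiff(names(conductances), names(g))
    if (length(bad)) stop("unknown conductance name(s): ",
                          paste(bad, collapse = ", "))
    if (any(conductances < 0)) stop("conductances must be non-negative")
    g[names(conductances)] <- conductances
  }
  bg <- modifyList(list(ex = 0.7, inf = 0.85, ins = 0.6,
                        ex_heterogeneity = 0.1), as.list(background))
  if (length(synaptic_delay) == 1)
    synaptic_delay <- rep(synaptic_delay, 4)
  if (is.null(names(synaptic_delay)) || !all(c("ampa", "nmda", "gaba_fast",
                                               "gaba_slow") %in% names(synaptic_delay)))
    names(synaptic_delay) <- c("ampa", "nmda", "gaba_fast", "gaba_slow")
  if (any(synaptic_delay < 0)) stop("synaptic delays must be non-negative")
  cfg <- structure(list(n_ex = n_ex, n_inf = n_inf, n_ins = n_ins,
                        conductances = g, connectivity = connectivity, p = p,
                        background = bg, neuron_ex = neuron_ex,
                        neuron_in = neuron_in, kinetics = kinetics,
                        conductance_scaling = conductance_scaling,
                        mg_conc = mg_conc, synaptic_delay = synaptic_delay,
                        dt = dt, duration = duration,
                        warmup = warmup, record_dt = record_dt,
                        seed = as.integer(seed)),
                   class = "tg_config")
  validate_config(cfg)
  cfg
}

#' Validate a network configuration
#'
#' Hard errors on structural problems (negative conductances, invalid
#' connection probability, non-positive sizes); values outside the printed
#' plausible ranges only raise warnings, since the published table itself
#' uses out-of-range values in places.
#'
#' @param config a `tg_config`
#' @param warn_ranges emit warnings for out-of-range conductances?
#' @return `config`, invisibly
#' @export
validate_config <- function(config, warn_ranges = FALSE) {
  stopifnot(inherits(config, "tg_config"))
  g <- config$conductances
  if (any(g < 0)) stop("negative conductance")
  if (config$connectivity == "bernoulli" &&
      (config$p <= 0 || config$p > 1))
    stop("connection probability p must lie in (0, 1]")
  if (warn_ranges) {
    for (nm in names(.tg_conductance_ranges)) {
      r <- .tg_conductance_ranges[[nm]]
      # the published default of g_GAss itself sits outside its printed
      # range (a defect of the printed table), so defaults never warn
      if (g[[nm]] == .tg_conductance_defaults[[nm]]) next
      if (g[[nm]] < r[1] || g[[nm]] > r[2])
        warning(sprintf("%s = %g outside the printed plausible range [%g, %g]",
                        nm, g[[nm]], r[1], r[2]), call. = FALSE)
    }
  }
  invisible(config)
}

#' Printed plausible ranges of the coupling conductances
#'
#' @return named list of `c(lo, hi)` ranges (uS) for the 12 couplings
#' @export
conductance_ranges <- function() .tg_conductance_ranges

#' Stimulus protocol
#'
#' A rectangular current pulse applied to the EX population only,
#' representing a transient sensory stimulus.
#'
#' @param amplitude pulse amplitude (nA); published default 0.8, explored
#'   range 0.5-1.5
#' @param onset pulse onset (ms)
#' @param duration pulse duration (ms)
#' @return an object of class `tg_stimulus`
#' @export
stimulus_protocol <- function(amplitude = 0.8, onset = 500, duration = 300) {
  stopifnot(duration >= 0, onset >= 0)
  structure(list(amplitude = amplitude, onset = onset, duration = duration,
                 target = "EX"), class = "tg_stimulus")
}

#' Named configuration presets
#'
#' * `table1_default`: the published 100/50/50 all-to-all parameter set.
#' * `sparse_p08`: same sizes and couplings, Bernoulli connectivity with
#'   p = 0.8.
#' * `large_sparse_p06`: the 200/100/100, p = 0.6 set with its own published
#'   coupling values.
#'
#' @param name preset name
#' @param ... overrides passed on to [network_config()]
#' @return a `tg_config`
#' @export
tg_preset <- function(name = c("table1_default", "sparse_p08",
                               "large_sparse_p06"), ...) {
  name <- match.arg(name)
  switch(name,
    table1_default = network_config(...),
    sparse_p08 = network_config(connectivity = "bernoulli", p = 0.8, ...),
    large_sparse_p06 = network_config(
      n_ex = 200, n_inf = 100, n_ins = 100,
      connectivity = "bernoulli", p = 0.6,
      conductances = c(g_GAfe = 0.015, g_GAse = 0.06, g_NMee = 0.002,
                       g_NMes = 0.0003, g_AMee = 0.007, g_AMef = 0.08,
                       g_NMef = 0.003, g_GAff = 0.08, g_GAfs = 0.0,
                       g_GAsf = 0.1, g_AMes = 0.005, g_GAss = 0.08), ...))
}

# Deterministic substream seeds: independent named consumers of the one run
# seed, so adding a consumer never perturbs the draws of the others.
tg_substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# evaluate expr under a named substream without disturbing the caller's RNG
with_substream <- function(seed, name, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(tg_substream_seed(seed, name))
  expr
}
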