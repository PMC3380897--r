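#' Leaky integrate-and-fire neuron parameters
#'
#' Bundles the membrane constants of one population: a spike is emitted when
#' the membrane potential crosses `threshold`, after which the potential is
#' clamped at `reset_potential` for `refractory_period` milliseconds.
#' Subthreshold dynamics follow
#' \deqn{C \, dV/dt = -g_L (V - V_{rest}) + I_{syn} + I_{ext}.}
#'
#' @param capacitance membrane capacitance (nF)
#' @param leak_conductance leak conductance (uS); membrane time constant is
#'   `capacitance / leak_conductance` ms
#' @param resting_potential leak reversal (mV)
#' @param threshold firing threshold (mV)
#' @param reset_potential post-spike reset value (mV); must lie below
#'   `threshold`
#' @param refractory_period absolute refractory period (ms)
#' @return an object of class `tg_neuron_params`
#' @examples
#' neuron_params() # excitatory-cell defaults
#' @export
neuron_params <- function(capacitance = 0.5, leak_conductance = 0.065,
                          resting_potential = -70, threshold = -52,
                          reset_potential = -60, refractory_period = 2) {
  stopifnot(capacitance > 0, leak_conductance > 0,
            reset_potential < threshold, refractory_period >= 0)
  structure(list(capacitance = capacitance,
                 leak_conductance = leak_conductance,
                 resting_potential = resting_potential,
                 threshold = threshold,
                 reset_potential = reset_potential,
                 refractory_period = refractory_period),
            class = "tg_neuron_params")
}

#' Synaptic receptor kinetics
#'
#' Describes one of the four receptor classes.  AMPA and NMDA use two-stage
#' kinetics: an auxiliary variable `x` jumps by 1 at each presynaptic spike
#' and decays with `rise_time_constant`, and the gating variable `s` relaxes
#' as \eqn{ds/dt = \alpha x (1 - s) - s/\tau_{decay}}, which saturates below
#' 1 for arbitrary spike trains.  The two GABA-A classes use single-stage
#' kinetics: `s` decays exponentially with `decay_time_constant` and at a
#' presynaptic spike jumps as \eqn{s \to s + j (1 - s)} using the value of
#' `s` immediately before the spike (`jump` = 1 saturates fully).
#'
#' The slow GABA-A decay lives on the theta timescale (order 100 ms) and the
#' fast one on the gamma timescale (order 5-10 ms); this kinetic separation
#' is what lets one network carry both rhythms.
#'
#' @param receptor_class one of `"AMPA"`, `"NMDA"`, `"GABA_fast"`,
#'   `"GABA_slow"`
#' @param rise_time_constant rise time constant (ms); only used by the
#'   two-stage classes
#' @param decay_time_constant decay time constant (ms)
#' @param reversal_potential synaptic reversal (mV)
#' @param gain drive rate \eqn{\alpha} (1/ms) of the two-stage kinetics
#' @param jump per-spike saturating increment fraction of the single-stage
#'   kinetics, in (0, 1]
#' @return an object of class `tg_synapse_kinetics`
#' @export
synapse_kinetics <- function(receptor_class = c("AMPA", "NMDA", "GABA_fast",
                                                "GABA_slow"),
                             rise_time_constant = NULL,
                             decay_time_constant = NULL,
                             reversal_potential = NULL,
                             gain = NULL, jump = 1) {
  receptor_class <- match.arg(receptor_class)
  defaults <- switch(receptor_class,
    AMPA      = list(rise = 0.5, decay = 2,   rev = 0,   gain = 1),
    NMDA      = list(rise = 2,   decay = 100, rev = 0,   gain = 0.5),
    GABA_fast = list(rise = NA,  decay = 8,   rev = -75, gain = NA),
    GABA_slow = list(rise = NA,  decay = 100, rev = -75, gain = NA))
  k <- structure(list(
    receptor_class = receptor_class,
    rise_time_constant = if (is.null(rise_time_constant)) defaults$rise else rise_time_constant,
    decay_time_constant = if (is.null(decay_time_constant)) defaults$decay else decay_time_constant,
    reversal_potential = if (is.null(reversal_potential)) defaults$rev else reversal_potential,
    gain = if (is.null(gain)) defaults$gain else gain,
    jump = jump), class = "tg_synapse_kinetics")
  stopifnot(k$decay_time_constant > 0, k$jump > 0, k$jump <= 1)
  k
}

#' Create a neuron state
#'
#' @param membrane_potential initial potential (mV)
#' @param refractory_remaining remaining absolute refractory time (ms)
#' @return an object of class `tg_neuron_state`
#' @export
neuron_state <- function(membrane_potential, refractory_remaining = 0) {
  structure(list(membrane_potential = membrane_potential,
                 refractory_remaining = refractory_remaining),
            class = "tg_neuron_state")
}

#' Advance one membrane time step
#'
#' Forward-Euler update of the leaky integrate-and-fire equation with
#' threshold/reset spiking and absolute refractoriness (potential clamped at
#' the reset value while refractory).  This scalar version defines the
#' reference semantics that the compiled network simulator replicates.
#'
#' @param state a [neuron_state()]
#' @param params a [neuron_params()]
#' @param synaptic_current synaptic input current (nA)
#' @param external_current external input current (nA)
#' @param dt time step (ms)
#' @return list with elements `state` (updated [neuron_state()]) and
#'   `spiked` (logical)
#' @export
step_membrane <- function(state, params, synaptic_current, external_current,
                          dt) {
  stopifnot(dt > 0)
  if (!is.finite(synaptic_current) || !is.finite(external_current) ||
      !is.finite(state$membrane_potential))
    stop("non-finite current or membrane potential: numerical blow-up ",
         "or inconsistent units")
  if (state$refractory_remaining > 0) {
    return(list(state = neuron_state(params$reset_potential,
                                     state$refractory_remaining - dt),
                spiked = FALSE))
  }
  v <- state$membrane_potential
  v_new <- v + dt / params$capacitance *
    (-params$leak_conductance * (v - params$resting_potential) +
       synaptic_current + external_current)
  if (!is.finite(v_new))
    stop("membrane potential diverged: numerical blow-up or bad units")
  if (v_new >= params$threshold) {
    list(state = neuron_state(params$reset_potential,
                              params$refractory_period),
         spiked = TRUE)
  } else {
    list(state = neuron_state(v_new, 0), spiked = FALSE)
  }
}

#' Advance two-stage (AMPA/NMDA) gating one time step
#'
#' The gating pair is updated with an exponential-Euler step of
#' \eqn{ds/dt = \alpha x (1-s) - s/\tau_d} (with \eqn{\alpha x} frozen over
#' the step), then the auxiliary variable decays exactly, then jumps by 1 if
#' a presynaptic spike arrived in this step.  Guarantees `s` stays in
#' `[0, 1)` for any spike train.
#'
#' @param gating list with fields `x` (auxiliary) and `s` (gating)
#' @param presyn_spike logical, presynaptic spike in this step
#' @param kinetics a [synapse_kinetics()] of class AMPA or NMDA
#' @param dt time step (ms)
#' @return updated gating list
#' @export
update_gating_two_stage <- function(gating, presyn_spike, kinetics, dt) {
  stopifnot(kinetics$receptor_class %in% c("AMPA", "NMDA"))
  if (!all(is.finite(c(gating$x, gating$s)))) stop("non-finite gating state")
  a <- kinetics$gain * gating$x
  denom <- a + 1 / kinetics$decay_time_constant
  dec <- exp(-denom * dt)
  s <- gating$s * dec + (a / denom) * (1 - dec)
  x <- gating$x * exp(-dt / kinetics$rise_time_constant)
  if (isTRUE(presyn_spike)) x <- x + 1
  list(x = x, s = s)
}

#' Advance single-stage (GABA-A) gating one time step
#'
#' Exponential decay with the class time constant; at a presynaptic spike
#' the gating jumps using its value immediately before the spike,
#' \eqn{s \to s + j(1-s)}, so it stays in `[0, 1]`.
#'
#' @param gating scalar gating value
#' @param presyn_spike logical
#' @param kinetics a [synapse_kinetics()] of class GABA_fast or GABA_slow
#' @param dt time step (ms)
#' @return updated gating value
#' @export
update_gating_single_stage <- function(gating, presyn_spike, kinetics, dt) {
  stopifnot(kinetics$receptor_class %in% c("GABA_fast", "GABA_slow"))
  if (!is.finite(gating)) stop("non-finite gating state")
  s <- gating * exp(-dt / kinetics$decay_time_constant)
  if (isTRUE(presyn_spike)) s <- s + kinetics$jump * (1 - s)
  s
}

#' NMDA magnesium-block factor
#'
#' Conventional sigmoidal voltage dependence
#' \eqn{B(V) = 1 / (1 + [Mg] e^{-0.062 V} / 3.57)} with the magnesium
#' concentration in mM.
#'
#' @param v membrane potential (mV)
#' @param mg_conc magnesium concentration (mM)
#' @param slope,scale shape constants of the standard parameterisation
#' @return block factor in (0, 1)
#' @export
mg_block <- function(v, mg_conc = 1, slope = 0.062, scale = 3.57) {
  1 / (1 + mg_conc * exp(-slope * v) / scale)
}

#' Total synaptic current onto one neuron
#'
#' Each receptor class contributes \eqn{-g \, s \, (V - E_{rev})}; the NMDA
#' term additionally carries the voltage-dependent magnesium-block factor.
#' `gatings` holds the summed afferent gating per class.
#'
#' @param gatings named numeric vector with entries among `ampa`, `nmda`,
#'   `gaba_fast`, `gaba_slow` (summed gating, dimensionless)
#' @param conductances named numeric vector (uS), same names
#' @param v postsynaptic membrane potential (mV)
#' @param kinetics named list of [synapse_kinetics()] keyed `ampa`, `nmda`,
#'   `gaba_fast`, `gaba_slow` (defaults used when omitted)
#' @param mg_conc magnesium concentration (mM) for the NMDA block
#' @return total synaptic current (nA)
#' @export
synaptic_current <- function(gatings, conductances, v,
                             kinetics = default_kinetics_table(),
                             mg_conc = 1) {
  classes <- names(gatings)
  if (is.null(classes) || !all(classes %in% names(kinetics)))
    stop("unknown receptor class in `gatings`: configuration error")
  stopifnot(all(conductances[classes] >= 0))
  total <- 0
  for (cl in classes) {
    e_rev <- kinetics[[cl]]$reversal_potential
    contrib <- -conductances[[cl]] * gatings[[cl]] * (v - e_rev)
    if (cl == "nmda") contrib <- contrib * mg_block(v, mg_conc)
    total <- total + contrib
  }
  total
}

#' Default kinetics table for the four receptor classes
#'
#' @return named list of [synapse_kinetics()] keyed `ampa`, `nmda`,
#'   `gaba_fast`, `gaba_slow`
#' @export
default_kinetics_table <- function() {
  list(ampa = synapse_kinetics("AMPA"),
       nmda = synapse_kinetics("NMDA"),
       gaba_fast = synapse_kinetics("GABA_fast"),
       gaba_slow = synapse_kinetics("GABA_slow"))
}
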