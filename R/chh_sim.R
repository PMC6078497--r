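## Cortical Hodgkin-Huxley (CHH) network variant: conductance-based
## regular-spiking neurons with Na, fast K, slow (M-type) K and leak
## currents, temperature dependence through Q10 factors.

#' CHH membrane and synapse parameters
#'
#' Defaults are the aperiodic-network CHH settings: regular-spiking
#' cortical kinetics at the reference temperature of 36 degrees C, with
#' conductance amplitudes carrying a Q10 of 1.3 and time constants a Q10
#' of 3. The gate rate functions (for n, m, h and the slow 'q' gate) are
#' the published regular-spiking cortical set, kept in one place
#' (\code{VT}, \code{tau_max_q}) so they can be swapped.
#'
#' @param Cm membrane capacitance (uF/cm^2).
#' @param gbar_L,gbar_K,gbar_M,gbar_Na maximal conductances (mS/cm^2).
#' @param Vbar_L,Vbar_K,Vbar_Na reversal potentials (mV).
#' @param Vbar_E,Vbar_I synaptic reversal potentials (mV).
#' @param I0 constant bias current (uA/cm^2).
#' @param T0 reference temperature (degrees C).
#' @param Q10a,Q10tau thermal factors for amplitudes and time constants.
#' @param eta_scale rescale applied to the weight-table strengths for
#'   conductance-based runs.
#' @param VT spike-threshold shift of the rate functions (mV).
#' @param tau_max_q maximal time constant of the slow K gate (ms).
#' @return object of class \code{chh_params}.
#' @export
chh_params <- function(Cm = 1, gbar_L = 0.1, gbar_K = 5, gbar_M = 0.07,
                       gbar_Na = 50, Vbar_L = -70, Vbar_K = -90,
                       Vbar_Na = 50, Vbar_E = 0, Vbar_I = -80, I0 = 3,
                       T0 = 36, Q10a = 1.3, Q10tau = 3,
                       eta_scale = 0.0015, VT = -56.2, tau_max_q = 1000) {
  p <- list(Cm = Cm, gbar_L = gbar_L, gbar_K = gbar_K, gbar_M = gbar_M,
            gbar_Na = gbar_Na, Vbar_L = Vbar_L, Vbar_K = Vbar_K,
            Vbar_Na = Vbar_Na, Vbar_E = Vbar_E, Vbar_I = Vbar_I, I0 = I0,
            T0 = T0, Q10a = Q10a, Q10tau = Q10tau, eta_scale = eta_scale,
            VT = VT, tau_max_q = tau_max_q,
            T = T0, gate_rate_factor = 1, w_factor = 1,
            tau_syn_factor = 1)
  class(p) <- "chh_params"
  p
}

#' Network configuration preset for CHH runs
#'
#' The aperiodic topology with the integration step, synaptic time
#' constant and velocity gain used for conductance-based simulations.
#'
#' @param ... overrides passed to \code{\link{network_config}}.
#' @return a \code{grid_network_config}.
#' @export
chh_config <- function(...) {
  network_config(topology = "aperiodic", dt = 0.025, tau_syn = 15,
                 beta_vel = 0.8, ...)
}

#' Total ionic current density of a CHH cell
#'
#' \eqn{I = g_L(V - V_L) + g_K n^4 (V - V_K) + g_M q (V - V_K) +
#' g_{Na} m^3 h (V - V_{Na})}.
#'
#' @param V membrane potential (mV); vectorized.
#' @param n,m,h,q gating variables in [0, 1].
#' @param params a \code{\link{chh_params}}.
#' @return current density (uA/cm^2).
#' @export
ionic_current <- function(V, n, m, h, q, params) {
  with(params,
       gbar_L * (V - Vbar_L) + gbar_K * n^4 * (V - Vbar_K) +
         gbar_M * q * (V - Vbar_K) + gbar_Na * m^3 * h * (V - Vbar_Na))
}

#' Synaptic current density into CHH cells
#'
#' \eqn{I^{syn}_i = \alpha_{vel}[g^{rec,E}_i(V_i - V_E) +
#' g^{rec,I}_i(V_i - V_I) - I_0] A_i} with
#' \eqn{g^{rec}} the weight-summed synaptic activations per source
#' population. Conductances are magnitudes, with the inhibitory sign
#' entering through the reversal potential; the constant bias \code{I0}
#' is depolarizing (it seeds network activity), so it carries the
#' opposite sign to the conductance terms in the voltage equation.
#'
#' @param V membrane potentials (full cell vector, order EL, ER, I).
#' @param weights a \code{grid_weight_matrix} (magnitudes; should carry
#'   the CHH \code{eta_scale} already, see \code{\link{run_chh}}).
#' @param s synaptic activations (full cell vector).
#' @param alpha_vel velocity modulation per cell.
#' @param A envelope per cell.
#' @param params a \code{\link{chh_params}}.
#' @param config the matching \code{\link{network_config}}.
#' @return current density per cell (uA/cm^2).
#' @export
synaptic_current <- function(V, weights, s, alpha_vel, A, params, config) {
  n <- length(V)
  WEI <- split_conductance_W(weights, config)
  gE <- as.numeric(WEI$WE %*% s)
  gI <- as.numeric(WEI$WI %*% s)
  alpha_vel * (gE * (V - params$Vbar_E) + gI * (V - params$Vbar_I) -
                 params$I0) * A
}

split_conductance_W <- function(weights, config) {
  n <- config$N_EL + config$N_ER + config$N_I
  WE <- matrix(0, n, n); WI <- matrix(0, n, n)
  for (nm in names(weights$blocks)) {
    tp <- block_target(nm); sp <- block_source(nm)
    B <- weights$blocks[[nm]]
    ri <- pop_offset(config, tp) + seq_len(nrow(B))
    ci <- pop_offset(config, sp) + seq_len(ncol(B))
    if (sp == "I") WI[ri, ci] <- WI[ri, ci] + B
    else WE[ri, ci] <- WE[ri, ci] + B
  }
  list(WE = WE, WI = WI)
}

#' Temperature (Q10) scaling of CHH parameters
#'
#' Scales conductance amplitudes by \eqn{Q_{10,a}^{(T - T_{ref})/10}} and
#' time constants by the inverse of \eqn{Q_{10,\tau}^{(T - T_{ref})/10}}
#' (cooling weakens conductances and slows kinetics), relative to the
#' parameters' current temperature. \code{mode} restricts the scaled
#' group: \code{"ionic_only"} scales the maximal conductances and gate
#' time constants while holding synaptic weights and \eqn{\tau_{syn}}
#' fixed; \code{"synaptic_only"} does the converse; \code{"all"} scales
#' both. The synaptic factors are recorded in the returned parameters
#' (\code{w_factor}, \code{tau_syn_factor}) and applied to a copy of the
#' weights at run time, never to the base weight matrix.
#'
#' @param params a \code{\link{chh_params}}.
#' @param T target temperature (degrees C, sanity range 20-40).
#' @param mode \code{"all"}, \code{"ionic_only"} or
#'   \code{"synaptic_only"}.
#' @return rescaled \code{chh_params} with \code{T} updated.
#' @export
q10_scale <- function(params, T, mode = c("all", "ionic_only",
                                          "synaptic_only")) {
  mode <- match.arg(mode)
  if (T < 20 || T > 40) stop("temperature outside the sanity range 20-40 C")
  fa <- params$Q10a^((T - params$T) / 10)
  ft <- params$Q10tau^((T - params$T) / 10)
  if (mode %in% c("all", "ionic_only")) {
    params$gbar_L <- params$gbar_L * fa
    params$gbar_K <- params$gbar_K * fa
    params$gbar_M <- params$gbar_M * fa
    params$gbar_Na <- params$gbar_Na * fa
    params$gate_rate_factor <- params$gate_rate_factor * ft
  }
  if (mode %in% c("all", "synaptic_only")) {
    params$w_factor <- params$w_factor * fa
    params$tau_syn_factor <- params$tau_syn_factor / ft
  }
  params$T <- T
  params
}

#' Simulate the CHH network along a trajectory
#'
#' Euler integration of the membrane equation with the regular-spiking
#' ionic currents and conductance-based recurrent synapses; spikes are
#' upward 0 mV crossings and drive the same exponential synapses as the
#' LNP model. Weight-table strengths are rescaled by
#' \code{params$eta_scale} and by the synaptic Q10 factor for the chosen
#' temperature; population activity frames are spike counts in 10 ms bins
#' smoothed with a 50 ms boxcar.
#'
#' @param config a \code{\link{chh_config}}-style configuration
#'   (aperiodic; \code{dt} = 0.025 ms).
#' @param weights unscaled \code{grid_weight_matrix} for the topology.
#' @param trajectory a \code{grid_trajectory} with matching \code{dt}.
#' @param temperature simulation temperature (degrees C).
#' @param q10_mode which parameter group feels the temperature change.
#' @param params base \code{\link{chh_params}}.
#' @param inh_scale extra scale on inhibitory conductances. The
#'   rate-model weight tables translate to conductances via
#'   \code{eta_scale}, but conductance inputs are weighted by their
#'   driving force, and near rest the inhibitory driving force
#'   (V - V_I of order 20 mV) is several-fold smaller than the
#'   excitatory one (V - V_E of order 60 mV); the default factor of 2
#'   restores the excitation-inhibition balance of the rate model so
#'   the network operates in its patterned regime.
#' @param seed integer seed.
#' @return as \code{\link{run_lnp}}: \code{spikes}, \code{activity},
#'   \code{config}, plus the scaled \code{params}.
#' @export
run_chh <- function(config, weights, trajectory, temperature = 36,
                    q10_mode = "all", params = chh_params(),
                    inh_scale = 2, seed = NULL) {
  if (abs(trajectory$dt - config$dt) > 1e-9)
    stop("trajectory dt does not match config dt")
  set.seed(if (is.null(seed)) config$seed else seed)
  p <- q10_scale(params, temperature, q10_mode)
  WEI <- split_conductance_W(weights, config)
  scale_w <- p$eta_scale * p$w_factor
  tau_syn <- config$tau_syn * p$tau_syn_factor
  A <- unlist(lapply(c("EL", "ER", "I"), function(pp) envelope_for(config, pp)))
  bin_ms <- 10
  res <- chh_core(WEI$WE * scale_w, WEI$WI * scale_w * inh_scale, A,
                  pop_dirs(config), config$beta_vel, trajectory$v,
                  config$dt, tau_syn,
                  c(p$Cm, p$gbar_L, p$gbar_K, p$gbar_M, p$gbar_Na,
                    p$Vbar_L, p$Vbar_K, p$Vbar_Na, p$Vbar_E, p$Vbar_I,
                    p$I0, p$VT, p$tau_max_q, p$gate_rate_factor),
                  as.integer(round(bin_ms / config$dt)))
  steps <- res$spike_step + 1L
  spikes <- data.frame(cell = res$spike_cell + 1L,
                       t_ms = trajectory$t[steps],
                       x_cm = trajectory$x[steps])
  ## counts (cells x bins) -> rates in Hz, 50 ms boxcar over 10 ms bins
  rate <- t(apply(res$counts, 1, boxcar_smooth, width = 5)) / (bin_ms / 1000)
  activity <- list(frames = rate,
                   frame_times = (seq_len(ncol(rate)) - 0.5) * bin_ms,
                   pop = pop_labels(config))
  class(activity) <- "population_activity"
  list(spikes = spikes, activity = activity, config = config, params = p,
       gate_range = c(res$gate_min, res$gate_max))
}
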