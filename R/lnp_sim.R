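## Linear-nonlinear-Poisson (sub-Poisson) spiking network simulation.

#' Threshold-linear transfer function
#'
#' @param x summed input.
#' @return \code{x} where positive, 0 otherwise.
#' @export
transfer <- function(x) pmax(x, 0)

pop_labels <- function(config) {
  c(rep("EL", config$N_EL), rep("ER", config$N_ER), rep("I", config$N_I))
}

pop_dirs <- function(config) {
  c(rep(-1, config$N_EL), rep(1, config$N_ER), rep(0, config$N_I))
}

pop_offset <- function(config, pop) {
  switch(pop, EL = 0L, ER = config$N_EL,
         I = config$N_EL + config$N_ER, stop("unknown population"))
}

#' Velocity modulation of the feedforward input
#'
#' \eqn{\alpha_{vel} = 1 + \beta_{vel} (v \cdot \hat e_P)}: a gain of 1 at
#' rest, increased (decreased) by motion along (against) the population's
#' preferred direction. Preferred directions are +1 for ER, -1 for EL and
#' 0 for I cells.
#'
#' @param v velocity along the track (m/s); vectorized.
#' @param dir preferred direction (+1, -1 or 0).
#' @param beta_vel velocity gain.
#' @return modulation factor(s).
#' @export
velocity_modulation <- function(v, dir, beta_vel) 1 + beta_vel * v * dir

## Combine blocks into one signed dense matrix in cell order EL, ER, I.
## Inhibitory-source columns carry negative sign (effective inhibition).
assemble_signed_W <- function(weights, config, sign_I = -1) {
  n <- config$N_EL + config$N_ER + config$N_I
  W <- matrix(0, n, n)
  for (nm in names(weights$blocks)) {
    tp <- block_target(nm); sp <- block_source(nm)
    B <- weights$blocks[[nm]]
    ri <- pop_offset(config, tp) + seq_len(nrow(B))
    ci <- pop_offset(config, sp) + seq_len(ncol(B))
    sgn <- if (sp == "I") sign_I else 1
    W[ri, ci] <- W[ri, ci] + sgn * B
  }
  W
}

#' Total synaptic input to every LNP cell
#'
#' Multiplicative mode:
#' \eqn{G_i = [\alpha_{vel}(G^{rec}_i + G_0) + G_0'] A_i}; additive mode:
#' \eqn{G_i = [W_{vel}\alpha_{vel} + G^{rec}_i + G_0 + G_0'] A_i}. The
#' recurrent input \eqn{G^{rec} = \sum W s} carries negative sign on
#' inhibitory-source blocks.
#'
#' @param s synaptic activation vector (cell order EL, ER, I).
#' @param weights a \code{grid_weight_matrix}.
#' @param config a \code{\link{network_config}}.
#' @param v instantaneous velocity (m/s).
#' @param mode \code{"multiplicative"} or \code{"additive"}; defaults to
#'   the config's \code{vel_mode}.
#' @return per-cell input vector G.
#' @export
total_input <- function(s, weights, config, v = 0, mode = NULL) {
  if (is.null(mode)) mode <- config$vel_mode
  W <- assemble_signed_W(weights, config)
  if (length(s) != nrow(W)) stop("activation vector does not match network size")
  Grec <- as.numeric(W %*% s)
  A <- unlist(lapply(c("EL", "ER", "I"), function(p) envelope_for(config, p)))
  alpha <- velocity_modulation(v, pop_dirs(config), config$beta_vel)
  G0p <- c(rep(config$G0p_EL, config$N_EL), rep(config$G0p_ER, config$N_ER),
           rep(config$G0p_I, config$N_I))
  if (mode == "multiplicative")
    (alpha * (Grec + config$G0) + G0p) * A
  else
    (config$W_vel * alpha + Grec + config$G0 + G0p) * A
}

#' Euler update of synaptic activation
#'
#' \eqn{s \leftarrow s(1 - dt/\tau_{syn}) + (\text{spikes this step})};
#' each spike adds a unit increment.
#'
#' @param s activation vector.
#' @param spikes spike counts this step (same length).
#' @param tau_syn synaptic time constant (ms).
#' @param dt time step (ms).
#' @return updated activations.
#' @export
synapse_step <- function(s, spikes, tau_syn, dt) {
  if (dt >= tau_syn) warning("dt >= tau_syn: Euler update unstable")
  s * (1 - dt / tau_syn) + spikes
}

#' Sub-Poisson spike generation by time-rescaled gamma renewal
#'
#' Generates spikes from a rate series via an integrate-and-threshold
#' renewal process: the integrated rate is compared against successive
#' draws of Gamma(shape = 1/CV^2, mean 1), giving an inter-spike-interval
#' coefficient of variation of CV at constant rate (CV = 0.5 with the
#' default gamma order 4) and a mean count of rate x duration.
#'
#' @param rate rate per step (spikes/s); scalar or vector over steps.
#' @param n_steps number of steps (when \code{rate} is scalar).
#' @param dt step (ms).
#' @param CV target ISI coefficient of variation.
#' @return integer vector of spike counts per step.
#' @export
spike_sample <- function(rate, n_steps = length(rate), dt = 0.5, CV = 0.5) {
  if (length(rate) == 1) rate <- rep(rate, n_steps)
  if (any(rate < 0)) stop("rate must be nonnegative")
  a <- 1 / CV^2
  H <- 0
  thr <- stats::rgamma(1, shape = a, rate = a)
  out <- integer(n_steps)
  for (t in seq_len(n_steps)) {
    H <- H + rate[t] * dt / 1000
    while (H >= thr) {
      out[t] <- out[t] + 1L
      thr <- thr + stats::rgamma(1, shape = a, rate = a)
    }
  }
  out
}

#' Synthetic 1D trajectory
#'
#' \code{"quasi_random"}: an Ornstein-Uhlenbeck-smoothed velocity process
#' (clipped to |v| <= 0.5 m/s) on a 200 cm track with reflecting
#' boundaries, covering the track with near-uniform occupancy.
#' \code{"constant_velocity"}: v(t) = v0 throughout (the track is
#' unbounded in this mode; position grows linearly). Reproducible given
#' the seed; velocity is flipped before a step that would leave the
#' track, so position increments always equal \code{v * dt} exactly.
#'
#' @param duration_s duration (s).
#' @param kind trajectory type.
#' @param v0 velocity for \code{constant_velocity} (m/s).
#' @param dt sampling step (ms).
#' @param track_length track length (cm).
#' @param seed integer seed (NULL = use current RNG state).
#' @return object of class \code{grid_trajectory}: \code{t} (ms),
#'   \code{x} (cm), \code{v} (m/s), \code{dt}, \code{track_length}.
#' @export
make_trajectory <- function(duration_s,
                            kind = c("quasi_random", "constant_velocity"),
                            v0 = 0, dt = 0.5, track_length = 200,
                            seed = NULL) {
  kind <- match.arg(kind)
  if (duration_s <= 0) stop("duration must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- ceiling(duration_s * 1000 / dt)
  dts <- dt / 1000
  if (kind == "constant_velocity") {
    v <- rep(v0, n)
    x <- track_length / 2 + c(0, cumsum(v[-n]) * dts * 100)
  } else {
    ## track-running locomotion: direction persists until a wall is hit,
    ## speed is an Ornstein-Uhlenbeck-smoothed positive process, so the
    ## track is swept in laps with near-uniform occupancy
    tau_s <- 1                          # speed OU time constant, s
    mu_s <- 0.25; sd_s <- 0.1           # mean and SD of speed, m/s
    sig <- sd_s * sqrt(2 / tau_s)
    v <- numeric(n); x <- numeric(n)
    x[1] <- track_length / 2
    dir <- if (stats::runif(1) < 0.5) -1 else 1
    spd <- mu_s
    eps <- stats::rnorm(n)
    for (k in seq_len(n)) {
      spd <- spd + (mu_s - spd) * dts / tau_s + sig * sqrt(dts) * eps[k]
      spd <- max(0.05, min(0.5, spd))
      if (k > 1) {
        xn <- x[k - 1] + dir * spd * dts * 100
        if (xn < 0 || xn > track_length) dir <- -dir
        x[k] <- x[k - 1] + dir * spd * dts * 100
      }
      v[k] <- dir * spd
    }
  }
  obj <- list(t = (seq_len(n) - 1) * dt, x = x, v = v, dt = dt,
              track_length = track_length, kind = kind)
  class(obj) <- "grid_trajectory"
  obj
}

#' Simulate the LNP spiking network along a trajectory
#'
#' Euler integration of the rate/spiking loop: recurrent input and
#' velocity drive set per-cell rates through the threshold-linear
#' transfer; spikes are drawn from the sub-Poisson renewal process and
#' activate exponentially decaying synapses. Returns the spike record
#' (with the animal position at each spike) and rate snapshots of the
#' population activity.
#'
#' @param config a \code{\link{network_config}}.
#' @param weights matching \code{grid_weight_matrix}.
#' @param trajectory a \code{grid_trajectory} with the same \code{dt}.
#' @param frame_every record a rate frame every this many steps.
#' @param max_frames keep at most this many trailing frames.
#' @param seed integer seed (NULL = config's seed).
#' @return list with \code{spikes} (data.frame \code{cell}, \code{t_ms},
#'   \code{x_cm}), \code{activity} (a \code{population_activity}: frames
#'   matrix cells x frames, \code{frame_times} ms, \code{pop} labels) and
#'   \code{config}.
#' @export
run_lnp <- function(config, weights, trajectory, frame_every = 1L,
                    max_frames = 10000L, seed = NULL) {
  if (abs(trajectory$dt - config$dt) > 1e-9)
    stop("trajectory dt does not match config dt")
  if (config$dt / config$tau_syn > 0.1)
    warning("dt/tau_syn > 0.1: integration may be inaccurate")
  set.seed(if (is.null(seed)) config$seed else seed)
  W <- assemble_signed_W(weights, config)
  A <- unlist(lapply(c("EL", "ER", "I"), function(p) envelope_for(config, p)))
  G0p <- c(rep(config$G0p_EL, config$N_EL), rep(config$G0p_ER, config$N_ER),
           rep(config$G0p_I, config$N_I))
  res <- lnp_core(W, A, G0p, pop_dirs(config), config$G0, config$beta_vel,
                  as.integer(config$vel_mode == "additive"), config$W_vel,
                  trajectory$v, config$dt, config$tau_syn, config$CV,
                  as.integer(frame_every), as.integer(max_frames))
  steps <- res$spike_step + 1L
  spikes <- data.frame(cell = res$spike_cell + 1L,
                       t_ms = trajectory$t[steps],
                       x_cm = trajectory$x[steps])
  activity <- list(frames = res$frames, frame_times = res$frame_times,
                   pop = pop_labels(config))
  class(activity) <- "population_activity"
  list(spikes = spikes, activity = activity, config = config)
}

#' Spike positions of one cell
#'
#' @param sim result of \code{\link{run_lnp}} or \code{\link{run_chh}}.
#' @param config the network config (for population offsets).
#' @param population population label.
#' @param index cell index within the population.
#' @return numeric vector of spike positions (cm).
#' @export
cell_spike_positions <- function(sim, config, population, index) {
  cell <- pop_offset(config, population) + index
  sim$spikes$x_cm[sim$spikes$cell == cell]
}

#' Synthetic spatially periodic spike map
#'
#' Inhomogeneous-Poisson spikes along a trajectory with a sinusoidal
#' spatial rate, \eqn{r(x) = r_0 (1 + \cos(2\pi x/\lambda + \phi))}.
#' Useful as ground-truth input for tuning-curve and bootstrap analyses.
#'
#' @param trajectory a \code{grid_trajectory}.
#' @param lambda spatial period (cm).
#' @param r0 mean rate (spikes/s).
#' @param phase phase offset (radians).
#' @return data.frame with \code{t_ms} and \code{x_cm} of the spikes.
#' @export
synth_spike_map <- function(trajectory, lambda = 50, r0 = 20, phase = 0) {
  r <- r0 * (1 + cos(2 * pi * trajectory$x / lambda + phase))
  p <- r * trajectory$dt / 1000
  keep <- stats::runif(length(p)) < p
  data.frame(t_ms = trajectory$t[keep], x_cm = trajectory$x[keep])
}
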