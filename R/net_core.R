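#' Network configuration for grid-cell circuit models
#'
#' Assembles the parameter set describing one of the three recurrent
#' architectures: \code{"aperiodic"} (local connectivity, free boundaries,
#' tapered envelope), \code{"partially_periodic"} (local connectivity on a
#' ring) and \code{"fully_periodic"} (ring with globally stretched
#' connectivity, periodicity scale \code{rho = 11}).
#'
#' The network has two excitatory populations (\code{EL}, \code{ER},
#' receiving leftward/rightward velocity input) and one inhibitory
#' population (\code{I}), with the default 5:1 E:I count ratio.
#'
#' @param topology one of \code{"aperiodic"}, \code{"partially_periodic"},
#'   \code{"fully_periodic"}.
#' @param N_EL,N_ER,N_I population sizes.
#' @param rho periodicity scale factor; defaults to 1 for aperiodic and
#'   partially periodic topologies and 11 for the fully periodic one.
#' @param dt integration time step (ms).
#' @param tau_syn synaptic activation time constant (ms).
#' @param beta_vel velocity gain (s/m; multiplies velocity in m/s).
#' @param gamma_inh inhibitory gain multiplier (1 = unperturbed).
#' @param CV target coefficient of variation of the spike point process.
#' @param G0 shared constant bias.
#' @param G0p_I,G0p_EL,G0p_ER population-specific constant biases.
#' @param W_vel additive-mode velocity weight.
#' @param kappa,a0 envelope range fraction and steepness (aperiodic only).
#' @param vel_mode \code{"multiplicative"} or \code{"additive"} velocity
#'   coupling.
#' @param ee_variant logical; use the connection tables that include
#'   excitatory-to-excitatory weights.
#' @param seed integer seed used by simulation runs.
#' @return an object of class \code{grid_network_config} (a list).
#' @export
network_config <- function(topology = c("aperiodic", "partially_periodic",
                                        "fully_periodic"),
                           N_EL = 400L, N_ER = 400L, N_I = 160L,
                           rho = NULL, dt = 0.5, tau_syn = 30,
                           beta_vel = 1, gamma_inh = 1, CV = 0.5,
                           G0 = 50, G0p_I = 0, G0p_EL = 15, G0p_ER = 15,
                           W_vel = 200, kappa = 0.3, a0 = 30,
                           vel_mode = c("multiplicative", "additive"),
                           ee_variant = FALSE, seed = 1L) {
  topology <- match.arg(topology)
  vel_mode <- match.arg(vel_mode)
  if (is.null(rho)) rho <- if (topology == "fully_periodic") 11 else 1
  if (dt <= 0 || tau_syn <= 0 || gamma_inh <= 0)
    stop("dt, tau_syn and gamma_inh must be positive")
  if (kappa <= 0 || kappa >= 1) stop("kappa must lie in (0, 1)")
  cfg <- list(topology = topology, N_EL = as.integer(N_EL),
              N_ER = as.integer(N_ER), N_I = as.integer(N_I), rho = rho,
              dt = dt, tau_syn = tau_syn, beta_vel = beta_vel,
              gamma_inh = gamma_inh, CV = CV, G0 = G0, G0p_I = G0p_I,
              G0p_EL = G0p_EL, G0p_ER = G0p_ER, W_vel = W_vel,
              kappa = kappa, a0 = a0, vel_mode = vel_mode,
              ee_variant = ee_variant, seed = as.integer(seed))
  class(cfg) <- "grid_network_config"
  cfg
}

#' @export
print.grid_network_config <- function(x, ...) {
  cat("grid network config:", x$topology,
      sprintf("(rho = %g)\n", x$rho))
  cat(sprintf("  N_EL = %d, N_ER = %d, N_I = %d\n", x$N_EL, x$N_ER, x$N_I))
  cat(sprintf("  dt = %g ms, tau_syn = %g ms, gamma_inh = %g, CV = %g\n",
              x$dt, x$tau_syn, x$gamma_inh, x$CV))
  invisible(x)
}

pop_size <- function(config, pop) {
  switch(pop, EL = config$N_EL, ER = config$N_ER, I = config$N_I,
         stop("unknown population: ", pop))
}

#' Circular (wrapped) distance in neuron index space
#'
#' \code{wrap_norm(x, N) = min(N - |x|, |x|)}: the distance between index
#' offsets on a ring of \code{N} neurons. Always lies in \code{[0, N/2]}.
#'
#' @param x signed offset (neurons); may be a vector or matrix.
#' @param N ring size (number of neurons in the population).
#' @return nonnegative wrapped distance, same shape as \code{x}.
#' @export
wrap_norm <- function(x, N) {
  if (N <= 0) stop("N must be positive")
  ax <- abs(x) %% N
  pmin(N - ax, ax)
}

#' Envelope taper for aperiodic networks
#'
#' Smooth taper applied to both activity and weights in the aperiodic
#' topology: equal to 1 within a central fraction \code{kappa} of the
#' network and decaying as a Gaussian in the rescaled distance beyond it,
#' \eqn{A_i = \exp[-a_0 ((r_i - \kappa N)/((1-\kappa)N))^2]} with
#' \eqn{r_i = |i - N/2|}.
#'
#' @param i neuron index, 0-based (\code{0 <= i < N}); vectorized.
#' @param N population size.
#' @param kappa fraction of the network over which the envelope is flat.
#' @param a0 steepness of the taper.
#' @return envelope values in (0, 1].
#' @export
envelope_value <- function(i, N, kappa = 0.3, a0 = 30) {
  if (kappa <= 0 || kappa >= 1) stop("kappa must lie in (0, 1)")
  r <- abs(i - N / 2)
  ifelse(r < kappa * N, 1, exp(-a0 * ((r - kappa * N) / ((1 - kappa) * N))^2))
}

envelope_for <- function(config, pop) {
  N <- pop_size(config, pop)
  if (config$topology == "aperiodic")
    envelope_value(seq_len(N) - 1L, N, config$kappa, config$a0)
  else rep(1, N)
}

#' Specification of one recurrent weight block
#'
#' Parameter bundle for a single connection block between two populations.
#' The shapes follow the mature-network profiles: shifted Gaussians for
#' E-to-I and E-to-E, a shifted Gaussian with a diagonal cut and a
#' direction-selective window for I-to-E, and a sum of two shifted
#' Gaussians with the central portion removed for I-to-I.
#'
#' @param kind one of \code{"E_to_I"}, \code{"I_to_E"}, \code{"I_to_I"},
#'   \code{"E_to_E"}.
#' @param source_pop,target_pop population labels (\code{"EL"}, \code{"ER"},
#'   \code{"I"}).
#' @param eta overall strength.
#' @param Delta centre shift (neurons).
#' @param sigma Gaussian width (neurons).
#' @param mu direction sign (+1/-1; I-to-E only).
#' @param delta_cut half-width of the central cut (neurons; I-to-E and
#'   I-to-I only).
#' @return an object of class \code{weight_block_spec}.
#' @export
weight_block_spec <- function(kind, source_pop, target_pop, eta, Delta,
                              sigma, mu = NULL, delta_cut = NULL) {
  kind <- match.arg(kind, c("E_to_I", "I_to_E", "I_to_I", "E_to_E"))
  if (eta <= 0 || sigma <= 0) stop("eta and sigma must be positive")
  if (!is.null(mu) && !mu %in% c(-1, 1)) stop("mu must be -1 or +1")
  structure(list(kind = kind, source_pop = source_pop,
                 target_pop = target_pop, eta = eta, Delta = Delta,
                 sigma = sigma, mu = mu, delta_cut = delta_cut),
            class = "weight_block_spec")
}

#' Default weight-block parameter tables
#'
#' The connection parameters of the mature network, for the standard
#' (inhibition-mediated) wiring and for the variant that adds
#' excitatory-to-excitatory connections.
#'
#' @param ee_variant logical; return the E-E variant tables.
#' @return named list of \code{\link{weight_block_spec}} objects.
#' @export
default_weight_specs <- function(ee_variant = FALSE) {
  if (!ee_variant) {
    list(
      I.EL  = weight_block_spec("E_to_I", "EL", "I", eta = 11.5, Delta = -2, sigma = 4),
      I.ER  = weight_block_spec("E_to_I", "ER", "I", eta = 11.5, Delta =  2, sigma = 4),
      EL.I  = weight_block_spec("I_to_E", "I", "EL", eta = 4, Delta =  8, sigma = 10,
                                mu = -1, delta_cut = 3),
      ER.I  = weight_block_spec("I_to_E", "I", "ER", eta = 4, Delta = -8, sigma = 10,
                                mu =  1, delta_cut = 3),
      I.I   = weight_block_spec("I_to_I", "I", "I", eta = 12, Delta = 4, sigma = 6,
                                delta_cut = 3)
    )
  } else {
    list(
      I.EL  = weight_block_spec("E_to_I", "EL", "I", eta = 3, Delta = -2, sigma = 8),
      I.ER  = weight_block_spec("E_to_I", "ER", "I", eta = 3, Delta =  2, sigma = 8),
      EL.I  = weight_block_spec("I_to_E", "I", "EL", eta = 3.25, Delta =  8, sigma = 8,
                                mu = -1, delta_cut = 3),
      ER.I  = weight_block_spec("I_to_E", "I", "ER", eta = 3.25, Delta = -8, sigma = 8,
                                mu =  1, delta_cut = 3),
      I.I   = weight_block_spec("I_to_I", "I", "I", eta = 4, Delta = 4, sigma = 6,
                                delta_cut = 3),
      EL.EL = weight_block_spec("E_to_E", "EL", "EL", eta = 5.5, Delta = -4, sigma = 4),
      ER.ER = weight_block_spec("E_to_E", "ER", "ER", eta = 5.5, Delta =  4, sigma = 4),
      ER.EL = weight_block_spec("E_to_E", "EL", "ER", eta = 5.5, Delta =  0, sigma = 4),
      EL.ER = weight_block_spec("E_to_E", "ER", "EL", eta = 5.5, Delta =  0, sigma = 4)
    )
  }
}

# Heaviside with Theta(0) = 1
heaviside <- function(x) (x >= 0) * 1

#' Build one recurrent weight block
#'
#' Constructs the dense matrix (target cells in rows, source cells in
#' columns) for a connection block. Offsets are measured in target-index
#' units, \code{x_ij = i - gamma*j} with \code{gamma = N_target/N_source}
#' kept real-valued. Periodic topologies use the wrapped norm on the target
#' ring with all shifts and widths scaled by \code{rho}; the aperiodic
#' topology replaces the wrapped norm by the absolute value and multiplies
#' by the product of source and target envelopes.
#'
#' Entries are connection magnitudes (all nonnegative); the inhibitory sign
#' is applied when blocks are summed into the recurrent input.
#'
#' @param spec a \code{\link{weight_block_spec}}.
#' @param config a \code{\link{network_config}}.
#' @return matrix of size \code{N_target x N_source}.
#' @export
build_weight_block <- function(spec, config) {
  Nt <- pop_size(config, spec$target_pop)
  Ns <- pop_size(config, spec$source_pop)
  rho <- config$rho
  gamma <- Nt / Ns
  x <- outer(seq_len(Nt), gamma * seq_len(Ns), `-`)   # x_ij = i - gamma j
  aper <- config$topology == "aperiodic"
  nrm <- if (aper) function(z) abs(z) else function(z) wrap_norm(z, Nt)
  g1 <- exp(-nrm(x - rho * spec$Delta)^2 / (2 * (spec$sigma * rho)^2))
  W <- switch(spec$kind,
    E_to_I = ,
    E_to_E = (spec$eta / rho) * g1,
    I_to_E = {
      mu <- spec$mu
      win <- heaviside(-mu * x) * heaviside(mu * x + Nt / 2) +
        heaviside(mu * x - Nt / 2)
      (spec$eta / rho) * g1 * heaviside(nrm(x) - rho * spec$delta_cut) * win
    },
    I_to_I = {
      g2 <- exp(-nrm(x + rho * spec$Delta)^2 / (2 * (spec$sigma * rho)^2))
      (spec$eta / rho) * (g1 + g2) * heaviside(nrm(x) - rho * spec$delta_cut)
    },
    stop("unknown block kind: ", spec$kind))
  if (aper) {
    At <- envelope_for(config, spec$target_pop)
    As <- envelope_for(config, spec$source_pop)
    W <- W * tcrossprod(At, As)
  }
  W
}

#' Build the full recurrent weight matrix
#'
#' Builds every connection block for the configured topology. Blocks store
#' magnitudes; blocks with inhibitory source enter the recurrent input sum
#' with negative sign (rate dynamics) or via the inhibitory reversal
#' potential (conductance dynamics).
#'
#' @param config a \code{\link{network_config}}.
#' @param specs optional list of \code{\link{weight_block_spec}}; defaults
#'   to \code{default_weight_specs(config$ee_variant)}.
#' @return object of class \code{grid_weight_matrix}: a list with
#'   \code{blocks} (named \code{"<target>.<source>"}), the generating
#'   \code{specs} and the applied inhibitory gain \code{gamma_inh}.
#' @export
build_weights <- function(config, specs = NULL) {
  if (is.null(specs)) specs <- default_weight_specs(config$ee_variant)
  blocks <- lapply(specs, build_weight_block, config = config)
  names(blocks) <- names(specs)
  w <- list(blocks = blocks, specs = specs, gamma_inh = 1)
  class(w) <- "grid_weight_matrix"
  w
}

block_source <- function(name) sub("^[^.]+\\.", "", name)
block_target <- function(name) sub("\\..*$", "", name)

#' Apply a global perturbation to weights and time constant
#'
#' Scales every block with inhibitory source by \code{gamma_inh} and the
#' synaptic time constant by \code{tau_scale}, leaving everything else
#' untouched. These are the two specific global perturbations whose
#' signatures in the population pattern discriminate circuit architectures.
#'
#' @param weights a \code{grid_weight_matrix}.
#' @param config the matching \code{\link{network_config}}.
#' @param gamma_inh multiplicative gain on inhibitory-source weights.
#' @param tau_scale multiplicative rescale of \code{tau_syn}.
#' @return list with elements \code{weights} and \code{config}, perturbed.
#' @export
apply_perturbation <- function(weights, config, gamma_inh = 1,
                               tau_scale = 1) {
  if (gamma_inh <= 0 || tau_scale <= 0)
    stop("gamma_inh and tau_scale must be positive")
  for (nm in names(weights$blocks)) {
    if (block_source(nm) == "I")
      weights$blocks[[nm]] <- weights$blocks[[nm]] * gamma_inh
  }
  weights$gamma_inh <- weights$gamma_inh * gamma_inh
  config$tau_syn <- config$tau_syn * tau_scale
  config$gamma_inh <- config$gamma_inh * gamma_inh
  list(weights = weights, config = config)
}

#' Export weight blocks to delimited text
#'
#' @param weights a \code{grid_weight_matrix}.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
export_weights <- function(weights, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(weights$blocks)) {
    p <- file.path(dir, paste0("W_", nm, ".tsv"))
    utils::write.table(weights$blocks[[nm]], p, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
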