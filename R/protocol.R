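## End-to-end perturbation protocol: simulate baseline and perturbed
## conditions, measure tuning and population statistics, build the DRPS
## against baseline, classify the architecture.

#' Measure one simulated condition
#'
#' Runs the LNP network over a quasi-random trajectory and computes the
#' standard measurement set: per-cell spatial tuning curves for a sampled
#' subset of analysis-eligible cells, mean tuning period and amplitude,
#' and the population pattern period and gridness.
#'
#' @param config a \code{\link{network_config}}.
#' @param weights matching \code{grid_weight_matrix}.
#' @param duration_s trajectory duration (s).
#' @param n_cells number of cells to sample for pairwise analysis.
#' @param population population analyzed.
#' @param seed integer seed (trajectory and spiking).
#' @param window frames averaged for population statistics.
#' @param track_length track length (cm); long enough to hold several
#'   grid periods.
#' @return list of measurements (see Details).
#' @export
measure_condition <- function(config, weights, duration_s = 60,
                              n_cells = 25, population = "I", seed = 1L,
                              window = 10000, track_length = 400) {
  traj <- make_trajectory(duration_s, "quasi_random", dt = config$dt,
                          track_length = track_length, seed = seed)
  sim <- run_lnp(config, weights, traj, max_frames = window, seed = seed + 1L)
  incl <- cells_included(config, population)
  ids <- if (length(incl) > n_cells)
    incl[round(seq(1, length(incl), length.out = n_cells))] else incl
  curves <- lapply(ids, function(i)
    tuning_curve(cell_spike_positions(sim, config, population, i), traj))
  periods <- vapply(curves, tuning_period, numeric(1))
  amps <- vapply(curves, tuning_amplitude, numeric(1))
  pop_stats <- population_spectrum_stats(sim$activity, population,
                                         window = window)
  list(cell_ids = ids, curves = curves,
       tuning_period = stats::median(periods, na.rm = TRUE),
       tuning_amplitude = mean(amps),
       pop_period = pop_stats$period, gridness = pop_stats$gridness,
       periods = periods, trajectory_seed = seed)
}

#' Pairwise relative phases of a measured condition
#'
#' @param meas result of \code{\link{measure_condition}}.
#' @return data.frame with pair indices \code{i}, \code{j} and
#'   \code{delta}; pairs with undefined phase are dropped.
#' @export
relative_phase_set <- function(meas) {
  n <- length(meas$curves)
  ij <- utils::combn(n, 2)
  delta <- vapply(seq_len(ncol(ij)), function(k) {
    tryCatch(relative_phase_1d(meas$curves[[ij[1, k]]],
                               meas$curves[[ij[2, k]]],
                               period = meas$tuning_period)$delta,
             error = function(e) NA_real_)
  }, numeric(1))
  out <- data.frame(i = ij[1, ], j = ij[2, ], delta = delta)
  out[is.finite(out$delta), ]
}

#' DRPS between two measured conditions
#'
#' Matches cell pairs across the two conditions and histograms the
#' relative-phase magnitude shifts \eqn{|\delta_{pre}| - |\delta_{post}|}.
#'
#' @param pre,post results of \code{\link{measure_condition}} on the same
#'   cell sample.
#' @return a \code{drps} object.
#' @export
condition_drps <- function(pre, post) {
  a <- relative_phase_set(pre)
  b <- relative_phase_set(post)
  key <- function(d) paste(d$i, d$j)
  common <- intersect(key(a), key(b))
  if (length(common) < 3) stop("too few matched pairs for a DRPS")
  sa <- a$delta[match(common, key(a))]
  sb <- b$delta[match(common, key(b))]
  drps_from_shifts(phase_magnitude(sa) - phase_magnitude(sb))
}

#' Run the full perturbation protocol on a simulated architecture
#'
#' Simulates the unperturbed baseline, then each perturbation strength in
#' turn; measures spatial tuning period/amplitude and the population
#' pattern in every condition; builds the DRPS of each perturbed
#' condition against baseline; and classifies the architecture from the
#' resulting series.
#'
#' @param topology network topology under test.
#' @param knob \code{"gamma_inh"} or \code{"tau_syn"}.
#' @param strengths non-baseline perturbation strengths (the baseline is
#'   the unperturbed value, 1).
#' @param duration_s trajectory duration per condition (s).
#' @param n_cells cells sampled for pairwise analysis.
#' @param population population analyzed.
#' @param seed integer seed.
#' @param config,weights optional pre-built network (defaults built from
#'   \code{topology}).
#' @return object of class \code{protocol_report}: per-condition
#'   measurements, the decision-tree input \code{series}, and the
#'   \code{classification}.
#' @export
run_protocol <- function(topology = "aperiodic",
                         knob = c("gamma_inh", "tau_syn"),
                         strengths = c(1.33, 1.66), duration_s = 60,
                         n_cells = 25, population = "I", seed = 1L,
                         config = NULL, weights = NULL,
                         track_length = 400) {
  knob <- match.arg(knob)
  if (length(strengths) < 1) stop("need at least one perturbation strength")
  if (is.null(config)) config <- network_config(topology, seed = seed)
  if (is.null(weights)) weights <- build_weights(config)
  base <- measure_condition(config, weights, duration_s, n_cells,
                            population, seed = seed,
                            track_length = track_length)
  conds <- list()
  series <- data.frame()
  for (k in seq_along(strengths)) {
    pert <- if (knob == "gamma_inh")
      apply_perturbation(weights, config, gamma_inh = strengths[k])
    else apply_perturbation(weights, config, tau_scale = strengths[k])
    m <- measure_condition(pert$config, pert$weights, duration_s, n_cells,
                           population, seed = seed + 100L * k,
                           track_length = track_length)
    d <- condition_drps(base, m)
    pk <- count_peaks(d)
    conds[[k]] <- list(strength = strengths[k], measurement = m, drps = d)
    series <- rbind(series, data.frame(
      strength = strengths[k],
      amplitude_change = relative_change(base$tuning_amplitude,
                                         m$tuning_amplitude),
      period_change = relative_change(base$tuning_period, m$tuning_period),
      pop_period_change = relative_change(base$pop_period, m$pop_period),
      drps_width = d$sigma, drps_peaks = pk$n_peaks))
  }
  rep <- list(topology = topology, knob = knob, baseline = base,
              conditions = conds, series = series,
              classification = classify_architecture(series),
              seed = seed)
  class(rep) <- "protocol_report"
  rep
}

#' @export
print.protocol_report <- function(x, ...) {
  cat("perturbation protocol:", x$topology, "network,", x$knob, "knob\n")
  print(x$series, row.names = FALSE)
  cat("classification:", x$classification$label, "\n")
  invisible(x)
}

#' Write synthetic analysis fixtures to disk
#'
#' Seeded generators for the analysis-only path: idealized 1D/2D phase
#' sets, spatially periodic Poisson spike maps, and constructed
#' DRPS-width-vs-strength series (ramp, step, flat) for classifier
#' checks. All outputs are delimited text.
#'
#' @param kind \code{"idealized_pattern"}, \code{"synthetic_spike_map"} or
#'   \code{"sigma_series"}.
#' @param params named list of generator parameters (see the respective
#'   generators for defaults).
#' @param seed integer seed.
#' @param out_dir output directory.
#' @return invisibly, the written file paths.
#' @export
generate_fixtures <- function(kind = c("idealized_pattern",
                                       "synthetic_spike_map",
                                       "sigma_series"),
                              params = list(), seed = 1L,
                              out_dir = tempdir()) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  if (kind == "idealized_pattern") {
    p <- utils::modifyList(list(N = 40, lambda_pop = 40 / 3, alpha = 0.1,
                                dims = 2), params)
    pat <- idealized_pattern(p$N, p$lambda_pop, p$alpha, p$dims)
    f <- file.path(out_dir, "idealized_phases.tsv")
    utils::write.table(data.frame(pre = I(pat$pre), post = I(pat$post)),
                       f, sep = "\t", row.names = FALSE)
    paths <- f
  } else if (kind == "synthetic_spike_map") {
    p <- utils::modifyList(list(duration_s = 120, lambda = 50, r0 = 20,
                                phase = 0, dt = 5), params)
    traj <- make_trajectory(p$duration_s, "quasi_random", dt = p$dt)
    sm <- synth_spike_map(traj, p$lambda, p$r0, p$phase)
    f <- file.path(out_dir, "spike_map.tsv")
    utils::write.table(sm, f, sep = "\t", row.names = FALSE)
    ft <- file.path(out_dir, "trajectory.tsv")
    utils::write.table(data.frame(t_ms = traj$t, x_cm = traj$x),
                       ft, sep = "\t", row.names = FALSE)
    paths <- c(f, ft)
  } else {
    p <- utils::modifyList(list(strengths = c(1.2, 1.4, 1.6)), params)
    ns <- length(p$strengths)
    mk <- function(shape, w) data.frame(shape = shape,
                                        strength = p$strengths,
                                        drps_width = w)
    ser <- rbind(mk("ramp", seq(0.04, 0.12, length.out = ns)),
                 mk("step", c(rep(0.005, ns - 1), 0.14)),
                 mk("flat", rep(0.004, ns)))
    f <- file.path(out_dir, "sigma_series.tsv")
    utils::write.table(ser, f, sep = "\t", row.names = FALSE)
    paths <- f
  }
  invisible(paths)
}

#' Read a spike map written by \code{\link{generate_fixtures}}
#'
#' @param path file with columns \code{t_ms}, \code{x_cm}.
#' @return data.frame of spike times and positions.
#' @export
read_spike_map <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
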