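## Spatial tuning curves and the population/tuning measures used to
## characterize simulated (or recorded) grid-cell responses.

boxcar_smooth <- function(x, width = 5) {
  ## centered boxcar, window truncated (and renormalized) at the edges
  n <- length(x)
  half <- (width - 1) / 2
  cs <- cumsum(c(0, x))
  lo <- pmax(1, seq_len(n) - floor(half))
  hi <- pmin(n, seq_len(n) + ceiling(half))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Occupancy-normalized spatial tuning curve
#'
#' Histograms spike positions into 1 cm bins, divides each bin count by
#' the time spent in it, and smooths with a 5-bin boxcar. Unvisited bins
#' are filled by linear interpolation before smoothing and flagged.
#'
#' @param spike_x spike positions (cm).
#' @param trajectory a \code{grid_trajectory} (provides occupancy).
#' @param bin_size spatial bin (cm).
#' @param smooth_bins boxcar width in bins.
#' @return object of class \code{tuning_curve}: list with
#'   \code{bin_edges}, \code{mids}, \code{rate} (spikes/s), \code{raw},
#'   \code{occupancy_s}, \code{visited}.
#' @export
tuning_curve <- function(spike_x, trajectory, bin_size = 1,
                         smooth_bins = 5) {
  L <- trajectory$track_length
  edges <- seq(0, L, by = bin_size)
  nb <- length(edges) - 1
  dts <- trajectory$dt / 1000
  occ <- graphics::hist(pmin(pmax(trajectory$x, 0), L - 1e-9),
                        breaks = edges, plot = FALSE)$counts * dts
  cnt <- graphics::hist(pmin(pmax(spike_x, 0), L - 1e-9),
                        breaks = edges, plot = FALSE)$counts
  visited <- occ > 0
  rate <- ifelse(visited, cnt / pmax(occ, .Machine$double.eps), NA_real_)
  if (any(!visited)) {
    if (!any(visited)) stop("trajectory visits no bins")
    mids <- (edges[-1] + edges[-(nb + 1)]) / 2
    rate <- stats::approx(mids[visited], rate[visited], xout = mids,
                          rule = 2)$y
  }
  obj <- list(bin_edges = edges, mids = (edges[-1] + edges[-(nb + 1)]) / 2,
              rate = boxcar_smooth(rate, smooth_bins), raw = rate,
              occupancy_s = occ, visited = visited, bin_size = bin_size)
  class(obj) <- "tuning_curve"
  obj
}

curve_rate <- function(curve) {
  if (inherits(curve, "tuning_curve")) curve$rate else as.numeric(curve)
}

curve_bin <- function(curve) {
  if (inherits(curve, "tuning_curve")) curve$bin_size else 1
}

#' Dominant spatial period of a tuning curve
#'
#' The inverse of the spatial frequency with the highest nonzero-frequency
#' peak in the power spectrum of the (mean-subtracted) curve. Returns NA
#' for a flat curve.
#'
#' @param curve a \code{tuning_curve} or numeric rate vector.
#' @return wavelength in the curve's spatial units (cm for 1 cm bins).
#' @export
tuning_period <- function(curve) {
  r <- curve_rate(curve)
  r <- r - mean(r)
  if (stats::sd(r) == 0) return(NA_real_)
  L <- length(r)
  p <- Mod(stats::fft(r))^2
  ks <- 2:(floor(L / 2) + 1)        # nonzero frequencies, unique half
  k <- ks[which.max(p[ks])]
  kf <- k - 1
  if (k > 2 && k < floor(L / 2) + 1 &&
      max(p[c(k - 1, k + 1)]) > 1e-8 * p[k]) {
    ## parabolic refinement of the peak frequency (log power), so that
    ## periods that do not divide the track length are not quantized;
    ## skipped for an exact spectral line (neighbours at round-off level)
    lp <- log(pmax(p[(k - 1):(k + 1)], 1e-300))
    den <- lp[1] - 2 * lp[2] + lp[3]
    if (den < 0) kf <- kf + max(-0.5, min(0.5, 0.5 * (lp[1] - lp[3]) / den))
  }
  (L / kf) * curve_bin(curve)
}

#' Mean rate density of a tuning curve
#'
#' @param curve a \code{tuning_curve} or numeric rate vector.
#' @return arithmetic mean of the smoothed rate across bins (spikes/s).
#' @export
tuning_amplitude <- function(curve) mean(curve_rate(curve))

#' Relative change of a measured quantity under perturbation
#'
#' \code{|post/pre - 1|}; applied to the spatial tuning period or
#' amplitude, or to the population period (where it is the stretch
#' factor).
#'
#' @param pre,post scalars; \code{pre} must be nonzero.
#' @return nonnegative relative change.
#' @export
relative_change <- function(pre, post) {
  if (any(pre == 0)) stop("pre-perturbation value must be nonzero")
  abs(post / pre - 1)
}

#' Relative phase between two spatially periodic tuning curves
#'
#' Cross-correlates the two mean-subtracted curves, finds the peak closest
#' to zero lag within one period, and expresses the offset as a fraction
#' of the shared tuning period, wrapped to [-1/2, 1/2). Positive offsets
#' mean curve \code{j} is shifted rightward relative to curve \code{i}.
#'
#' @param curve_i,curve_j \code{tuning_curve}s or rate vectors on the same
#'   bins.
#' @param period optional shared period (spatial units); estimated from
#'   the two curves when NULL (they must then agree within 10\%).
#' @param method \code{"fourier"} (default) locates the central
#'   cross-correlation peak from the phase of the cross-spectrum at the
#'   shared pattern frequency, which uses the whole curve and is robust
#'   to secondary-peak mis-picks on noisy curves; \code{"xcorr_peak"}
#'   scans the lagged cross-correlation directly (1-bin resolution).
#' @return list with \code{delta} (relative phase), \code{d} (offset,
#'   spatial units), \code{lambda} (shared period).
#' @export
relative_phase_1d <- function(curve_i, curve_j, period = NULL,
                              method = c("fourier", "xcorr_peak")) {
  method <- match.arg(method)
  ri <- curve_rate(curve_i); rj <- curve_rate(curve_j)
  if (length(ri) != length(rj)) stop("curves must share binning")
  bs <- curve_bin(curve_i)
  if (is.null(period)) {
    li <- tuning_period(curve_i); lj <- tuning_period(curve_j)
    if (is.na(li) || is.na(lj)) stop("flat tuning curve: period undefined")
    if (abs(li / lj - 1) > 0.10)
      stop("tuning periods disagree by more than 10%")
    period <- (li + lj) / 2
  }
  lam_bins <- period / bs
  ri <- ri - mean(ri); rj <- rj - mean(rj)
  if (stats::sd(ri) == 0 || stats::sd(rj) == 0)
    stop("flat tuning curve: relative phase undefined")
  L <- length(ri)
  if (method == "fourier") {
    k <- max(1, round(L / lam_bins))      # cycles of the pattern frequency
    fi <- stats::fft(ri)[k + 1]
    fj <- stats::fft(rj)[k + 1]
    th <- Arg(fi * Conj(fj))              # 2*pi*k*d/L for a shift d
    d <- th * L / (2 * pi * k) * bs
  } else {
    maxlag <- min(L - 1, ceiling(lam_bins))
    lags <- -maxlag:maxlag
    cc <- vapply(lags, function(l) {
      if (l >= 0) sum(ri[1:(L - l)] * rj[(1 + l):L]) / (L - l)
      else sum(ri[(1 - l):L] * rj[1:(L + l)]) / (L + l)
    }, numeric(1))
    pk <- local_maxima(cc)
    if (!length(pk)) pk <- which.max(cc)
    d <- lags[pk[which.min(abs(lags[pk]))]] * bs
  }
  list(delta = wrap_half(d / period), d = d, lambda = period)
}

#' Relative phase between two 2D rate maps
#'
#' Finds the displacement of the central peak of the circular 2D
#' cross-correlation of the two maps, obliquely projects it onto the
#' lattice principal vectors \code{lambda1*e1}, \code{lambda2*e2}, and
#' wraps each component into [-1/2, 1/2).
#'
#' @param map_i,map_j matrices on the same grid (periodic domain).
#' @param lattice list with \code{lambda1}, \code{e1}, \code{lambda2},
#'   \code{e2} (periods in grid units; axis unit vectors).
#' @return list with \code{delta} (length-2 wrapped phase) and \code{d}
#'   (displacement in grid units).
#' @export
relative_phase_2d <- function(map_i, map_j, lattice) {
  stopifnot(all(dim(map_i) == dim(map_j)))
  B <- cbind(lattice$lambda1 * lattice$e1, lattice$lambda2 * lattice$e2)
  if (abs(det(B)) < 1e-9) stop("degenerate lattice: parallel principal axes")
  a <- map_i - mean(map_i); b <- map_j - mean(map_j)
  cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE))
  n1 <- nrow(cc); n2 <- ncol(cc)
  ## displacement candidates wrapped to centered ranges; pick the
  ## cross-correlation peak closest to the origin
  pk <- which(cc >= 0.999 * max(cc), arr.ind = TRUE)
  wrapc <- function(k, n) ifelse(k - 1 > n / 2, k - 1 - n, k - 1)
  d1 <- wrapc(pk[, 1], n1); d2 <- wrapc(pk[, 2], n2)
  sel <- which.min(d1^2 + d2^2)
  d <- c(d1[sel], d2[sel])
  dp <- solve(B, d)
  list(delta = as.numeric(phase_wrap_2d(dp[1], dp[2])), d = d)
}

#' Spectral statistics of the population activity pattern
#'
#' For each frame of population activity: restrict to the middle half of
#' the population vector, normalize (mean subtraction, division by the
#' standard deviation), compute the power spectrum rescaled by
#' \eqn{2/L^2}, and take the power (gridness) and wavelength (population
#' period, in neurons) of the largest nonzero-frequency component.
#' Both are averaged over the last \code{window} frames; zero-variance
#' frames are skipped.
#'
#' @param activity a \code{population_activity} object (see
#'   \code{\link{run_lnp}}) or a cells-by-frames matrix.
#' @param population population label to analyze (when \code{activity}
#'   carries population labels); default \code{"I"}.
#' @param window number of trailing frames to average over.
#' @param middle_half restrict to indices [N/4, 3N/4) of the vector.
#' @return list with \code{period} (neurons), \code{gridness},
#'   \code{L}, \code{n_frames_used}, and the per-frame series.
#' @export
population_spectrum_stats <- function(activity, population = "I",
                                      window = 10000,
                                      middle_half = TRUE) {
  fr <- if (is.matrix(activity)) activity else activity$frames
  if (!is.matrix(activity) && !is.null(activity$pop))
    fr <- fr[activity$pop == population, , drop = FALSE]
  nf <- ncol(fr)
  use <- max(1, nf - window + 1):nf
  fr <- fr[, use, drop = FALSE]
  N <- nrow(fr)
  if (middle_half) fr <- fr[(floor(N / 4) + 1):floor(3 * N / 4), ,
                            drop = FALSE]
  L <- nrow(fr)
  mu <- colMeans(fr)
  fr <- sweep(fr, 2, mu)
  sds <- sqrt(colSums(fr^2) / L)
  ok <- sds > 1e-12
  if (!any(ok)) stop("all frames have zero variance: no pattern to measure")
  fr <- sweep(fr[, ok, drop = FALSE], 2, sds[ok], "/")
  P <- (2 / L^2) * Mod(stats::mvfft(fr))^2
  ks <- 2:(floor(L / 2) + 1)
  kmax <- ks[apply(P[ks, , drop = FALSE], 2, which.max)]
  gridness <- P[cbind(kmax, seq_len(ncol(P)))]
  kf <- vapply(seq_along(kmax), function(j) {
    k <- kmax[j]
    ## narrow-bump patterns put comparable power into harmonics of the
    ## bump spacing; when a subharmonic of the largest peak carries at
    ## least half its power, the subharmonic is the pattern frequency
    for (m in 3:2) {
      kc <- (k - 1) / m
      cand <- unique(pmax(1, c(floor(kc), ceiling(kc)))) + 1
      cand <- cand[cand >= 2 & cand < k]
      if (length(cand) && max(P[cand, j]) >= 0.5 * P[k, j]) {
        k <- cand[which.max(P[cand, j])]
        break
      }
    }
    ## parabolic interpolation (log power) refines the wavelength beyond
    ## the integer cycles-per-window quantization; skipped for an exact
    ## spectral line (neighbours at round-off level)
    if (k <= 2 || k >= floor(L / 2) + 1) return(k - 1)
    if (max(P[c(k - 1, k + 1), j]) <= 1e-8 * P[k, j]) return(k - 1)
    lp <- log(pmax(P[(k - 1):(k + 1), j], 1e-300))
    den <- lp[1] - 2 * lp[2] + lp[3]
    frac <- if (den < 0) 0.5 * (lp[1] - lp[3]) / den else 0
    (k - 1) + max(-0.5, min(0.5, frac))
  }, numeric(1))
  period <- L / kf
  list(period = mean(period), gridness = mean(gridness), L = L,
       n_frames_used = sum(ok), period_series = period,
       gridness_series = gridness)
}

#' Translation speed of the population pattern under fixed velocity input
#'
#' Simulates the network for a settling period plus \code{measure_s}
#' seconds at constant velocity, tracks the circular displacement of the
#' population pattern relative to a reference frame (sub-bin peak
#' interpolation, unwrapped modulo the population period), smooths the
#' displacement with a 4 s moving average and returns the mean speed over
#' the middle half of the measurement window.
#'
#' @param config a \code{\link{network_config}}.
#' @param weights matching \code{grid_weight_matrix}.
#' @param v_fixed input velocity (m/s).
#' @param settle_s settling time before measurement (s).
#' @param measure_s measurement duration (s).
#' @param population population to track.
#' @return pattern speed in neurons/s (signed; positive = increasing
#'   index).
#' @export
velocity_response <- function(config, weights, v_fixed, settle_s = 2,
                              measure_s = 10, population = "I") {
  traj <- make_trajectory(settle_s + measure_s, "constant_velocity",
                          v0 = v_fixed, dt = config$dt,
                          seed = config$seed)
  frame_every <- max(1L, round(10 / config$dt))  # ~10 ms frames
  sim <- run_lnp(config, weights, traj, frame_every = frame_every,
                 max_frames = ceiling((settle_s + measure_s) * 1000 /
                                        (config$dt * frame_every)))
  fr <- sim$activity$frames[sim$activity$pop == population, , drop = FALSE]
  ft <- sim$activity$frame_times
  keep <- ft >= settle_s * 1000
  fr <- fr[, keep, drop = FALSE]; ft <- ft[keep]
  st <- population_spectrum_stats(sim$activity, population, window = 2000)
  if (st$gridness < 0.1) stop("population activity is not patterned")
  lam <- st$period
  ref <- fr[, 1] - mean(fr[, 1])
  Fref <- Conj(stats::fft(ref))
  L <- length(ref)
  raw <- vapply(seq_len(ncol(fr)), function(k) {
    b <- fr[, k] - mean(fr[, k])
    cc <- Re(stats::fft(Fref * stats::fft(b), inverse = TRUE)) / L
    i0 <- which.max(cc)
    im <- if (i0 == 1) L else i0 - 1
    ip <- if (i0 == L) 1 else i0 + 1
    denom <- cc[im] - 2 * cc[i0] + cc[ip]
    frac <- if (denom != 0) 0.5 * (cc[im] - cc[ip]) / denom else 0
    s <- (i0 - 1) + frac
    if (s > L / 2) s <- s - L
    s
  }, numeric(1))
  ## unwrap: the pattern is periodic, so displacement is defined mod lam;
  ## choose the branch closest to the previous unwrapped value
  D <- numeric(length(raw))
  D[1] <- 0
  for (k in 2:length(raw)) {
    base <- raw[k] %% lam
    m <- round((D[k - 1] - base) / lam)
    D[k] <- base + m * lam
  }
  fdt <- diff(ft[1:2]) / 1000            # frame interval, s
  wma <- max(1, round(4 / fdt))          # 4 s moving average
  Ds <- boxcar_smooth(D, wma)
  v_inst <- diff(Ds) / fdt
  mid <- seq(floor(length(v_inst) / 4) + 1, floor(3 * length(v_inst) / 4))
  mean(v_inst[mid])
}

#' Indices of cells included in analyses
#'
#' All cells for periodic topologies; the central 3/4 of cells (best
#' spatial tuning, away from the envelope taper) for aperiodic networks.
#'
#' @param config a \code{\link{network_config}}.
#' @param population population label.
#' @return integer indices within the population.
#' @export
cells_included <- function(config, population = "I") {
  N <- pop_size(config, population)
  if (config$topology == "aperiodic")
    seq.int(floor(N / 8) + 1, floor(7 * N / 8))
  else seq_len(N)
}

#' Count activity bumps in a population profile
#'
#' Counts circular local maxima above a fraction of the profile maximum in
#' a time-averaged population activity profile. For ring (periodic)
#' topologies the bump count is an integer constrained by the symmetry of
#' the network, so perturbation-induced period changes appear as integer
#' jumps of this count.
#'
#' @param activity a \code{population_activity} or cells-by-frames matrix.
#' @param population population label.
#' @param avg_frames number of trailing frames to average.
#' @param min_frac detection threshold as a fraction of the profile max.
#' @return integer bump count.
#' @export
count_population_bumps <- function(activity, population = "I",
                                   avg_frames = 500, min_frac = 0.2) {
  fr <- if (is.matrix(activity)) activity else
    activity$frames[activity$pop == population, , drop = FALSE]
  nf <- ncol(fr)
  prof <- rowMeans(fr[, max(1, nf - avg_frames + 1):nf, drop = FALSE])
  n <- length(prof)
  up <- prof >= prof[c(n, 1:(n - 1))]
  dn <- prof > prof[c(2:n, 1)]
  sum(prof > min_frac * max(prof) & up & dn)
}
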