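make_traj <- function(dur = 120, dt = 5, seed = 21, L = 200)
  make_trajectory(dur, "quasi_random", dt = dt, track_length = L,
                  seed = seed)

test_that("tuning curves are occupancy-normalized and smoothed", {
  tr <- make_traj()
  set.seed(9)
  # homogeneous Poisson spikes at 12 Hz: flat curve near 12
  p <- 12 * tr$dt / 1000
  sm <- tr$x[stats::runif(length(tr$x)) < p]
  tc <- tuning_curve(sm, tr)
  expect_equal(mean(tc$rate), 12, tolerance = 3 * 12 / sqrt(length(sm)) / 3)
  expect_lt(stats::sd(tc$rate) / mean(tc$rate), 0.35)
  # no spikes: all-zero curve
  t0 <- tuning_curve(numeric(0), tr)
  expect_true(all(t0$rate == 0))
  # binning and smoothing conventions
  expect_equal(diff(tc$bin_edges)[1], 1)
  expect_equal(length(tc$rate), 200)
})

test_that("tuning period picks the strongest spectral component", {
  x <- seq(0, 199)
  expect_equal(tuning_period(10 + sin(2 * pi * x / 20)), 20)
  two <- 2 * sin(2 * pi * x / 20) + sin(2 * pi * x / 50)
  expect_equal(tuning_period(two), 20)          # larger power wins
  expect_true(is.na(tuning_period(rep(4, 200))))
})

test_that("tuning period scales linearly with a stretch of the curve", {
  x <- seq(0, 399)
  for (s in c(1, 1.25, 1.6)) {
    lam <- 25 * s
    per <- tuning_period(5 + sin(2 * pi * x / lam))
    expect_lt(abs(per - lam), 1)                 # within one bin
  }
})

test_that("tuning amplitude is the mean rate density", {
  expect_equal(tuning_amplitude(rep(0, 100)), 0)
  expect_equal(tuning_amplitude(rep(7.5, 100)), 7.5)
  set.seed(1); r <- stats::runif(200, 0, 30)
  expect_equal(tuning_amplitude(r), mean(r))     # brute-force oracle
})

test_that("relative change is |post/pre - 1|", {
  expect_equal(relative_change(10, 10), 0)
  expect_equal(relative_change(10, 11), 0.1)
  expect_equal(relative_change(8, 6), 0.25)
  expect_error(relative_change(0, 1), "nonzero")
})

test_that("relative phase recovers constructed shifts and is antisymmetric", {
  x <- seq(0, 199)
  lam <- 40
  ci <- 10 + 4 * cos(2 * pi * x / lam)
  for (shift in c(0, 5, 10, -8)) {
    cj <- 10 + 4 * cos(2 * pi * (x - shift) / lam)
    for (m in c("fourier", "xcorr_peak")) {
      rp <- relative_phase_1d(ci, cj, method = m)
      expect_equal(rp$delta, wrap_half(shift / lam), tolerance = 0.015)
    }
    # antisymmetry: delta(i,j) = -delta(j,i) mod 1
    d1 <- relative_phase_1d(ci, cj)$delta
    d2 <- relative_phase_1d(cj, ci)$delta
    expect_equal(wrap_half(d1 + d2), 0, tolerance = 1e-6)
  }
  expect_equal(relative_phase_1d(ci, ci)$delta, 0)
  expect_error(relative_phase_1d(rep(1, 200), ci), "flat")
  cj50 <- 10 + 4 * cos(2 * pi * x / 50)
  expect_error(relative_phase_1d(ci, cj50), "disagree")
})

test_that("2D relative phase wraps through the oblique projection", {
  expect_equal(as.numeric(phase_wrap_2d(0.7, 0.2)), c(-0.3, 0.2))
  expect_equal(as.numeric(phase_wrap_2d(0.2, 0.2)), c(0.2, 0.2))
  expect_equal(as.numeric(phase_wrap_2d(0.5, 0.5)), c(-0.5, -0.5))
  lat <- list(lambda1 = 10, e1 = c(1, 0), lambda2 = 10, e2 = c(0, 1))
  mk <- function(s1, s2) outer(0:39, 0:39, function(i, j)
    cos(2 * pi * (i - s1) / 10) + cos(2 * pi * (j - s2) / 10))
  rp <- relative_phase_2d(mk(0, 0), mk(2, -3), lat)
  expect_equal(rp$delta, c(0.2, -0.3), tolerance = 1e-6)
  expect_equal(relative_phase_2d(mk(1, 1), mk(1, 1), lat)$delta, c(0, 0))
  bad <- list(lambda1 = 10, e1 = c(1, 0), lambda2 = 10, e2 = c(1, 0))
  expect_error(relative_phase_2d(mk(0, 0), mk(0, 0), bad), "degenerate")
})

test_that("population spectrum scores a sinusoidal pattern as gridness 1", {
  fr <- sinusoid_frames(N = 160, cycles_in_middle_half = 4)
  st <- population_spectrum_stats(fr, window = 20)
  expect_equal(st$gridness, 1, tolerance = 0.02)
  expect_equal(st$period, 20, tolerance = 0.5)   # 80-bin window, 4 cycles
  expect_equal(st$L, 80)                         # middle half of 160
})

test_that("white-noise frames score low gridness", {
  set.seed(31)
  fr <- matrix(stats::rnorm(400 * 50), 400, 50)
  st <- population_spectrum_stats(fr, window = 50)
  expect_lt(st$gridness, 0.2)
  expect_equal(st$L, 200)                        # middle half of 400
})

test_that("gridness is bounded by 1 for normalized frames", {
  set.seed(32)
  for (k in 1:5) {
    fr <- matrix(stats::rnorm(120 * 10) + 3, 120, 10)
    st <- population_spectrum_stats(fr, window = 10)
    expect_gte(st$gridness, 0); expect_lte(st$gridness, 1 + 1e-9)
  }
})

test_that("analysis inclusion keeps all ring cells, central 3/4 otherwise", {
  expect_equal(cells_included(network_config("fully_periodic"), "I"),
               1:160)
  inc <- cells_included(network_config("aperiodic"), "I")
  expect_equal(length(inc), 120)
  expect_equal(range(inc), c(21, 140))
})

test_that("bump counting reads integer bump numbers off a profile", {
  prof <- 10 + 5 * cos(2 * pi * (0:159) / 16)    # 10 bumps on the ring
  expect_equal(count_population_bumps(matrix(prof, ncol = 1)), 10)
})
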