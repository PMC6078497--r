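test_that("population phase follows the stated convention", {
  expect_equal(population_phase(1, 20), 0)       # neuron 1 has phase 0
  expect_equal(population_phase(21, 20), 0)
  expect_equal(population_phase(11, 20), 0.5)
  expect_equal(population_phase(6, 40 / 3), ((5) %% (40 / 3)) / (40 / 3))
})

test_that("phase magnitude is the Lee distance", {
  expect_equal(phase_magnitude(0.7), 0.3)
  expect_equal(phase_magnitude(-0.4), 0.4)
  expect_equal(phase_magnitude(0.5), 0.5)
  expect_true(all(phase_magnitude(stats::runif(100, -3, 3)) <= 0.5))
})

test_that("the resolvability bound is 1/(2M)", {
  expect_equal(resolvability_bound(5), 0.1)
  expect_equal(round(resolvability_bound(7), 2), 0.07)
  expect_equal(shift_quantum(0.1), 0.1 / 1.1)
})

test_that("idealized patterns stretch about the first neuron", {
  p0 <- idealized_pattern(100, 20, 0)
  expect_equal(p0$pre, p0$post)
  p <- idealized_pattern(100, 20, 0.1)
  # a cell K periods from the focus shifts by K quanta (mod 1)
  K <- 3; i <- 1 + K * 20
  shift <- wrap_half(p$pre[i] - p$post[i])
  expect_equal(shift %% 1, (K * shift_quantum(0.1)) %% 1, tolerance = 1e-9)
  # 2D defaults follow the idealized-sheet parameter set
  p2 <- idealized_pattern(40, 40 / 3, 0.1, dims = 2)
  expect_equal(nrow(p2$pre), 1600)
  expect_equal(p2$M, c(3, 3))
})

test_that("DRPS pair counts and degenerate widths are exact", {
  p <- idealized_pattern(100, 20, 0.05)
  d <- drps(p$pre, p$post, "pairwise_relative")
  expect_equal(d$n, choose(100, 2))              # 4950 pairs
  expect_equal(sum(d$raw), d$n)                  # histogram holds the mass
  same <- drps(p$pre, p$pre, "pairwise_relative")
  expect_equal(same$sigma, 0)
  expect_true(all(same$shifts == 0))
})

test_that("quantal peak spacing equals the quantum of shift", {
  for (a in c(0.05, 0.1)) {
    p <- idealized_pattern(1000, 200, a)         # M = 5
    k <- count_peaks(drps(p$pre, p$post, "per_cell_population"))
    expect_lt(abs(k$spacing - shift_quantum(a)), 0.005 + 1e-9)  # one bin
  }
  # quanta finer than the smoothing resolution are read off the raw bins
  p <- idealized_pattern(2000, 400, 0.02)
  k <- count_peaks(drps(p$pre, p$post, "per_cell_population"),
                   smoothed = FALSE)
  expect_lt(abs(k$spacing - shift_quantum(0.02)), 0.005 + 1e-9)
})

test_that("peak count is twice the bump number below the aliasing bound", {
  for (ps in list(c(3, 0.05), c(5, 0.05), c(3, 0.1), c(5, 0.1))) {
    M <- ps[1]; a <- ps[2]
    p <- idealized_pattern(1000, 1000 / M, a)
    k <- count_peaks(drps(p$pre, p$post, "per_cell_population"))
    expect_equal(k$n_peaks, 2 * M)
  }
  # beyond M*Delta = 1/2 the wrapped peaks alias and the count drops
  p <- idealized_pattern(1000, 200, 0.2)         # M*Delta = 0.83
  k <- count_peaks(drps(p$pre, p$post, "per_cell_population"))
  expect_lt(k$n_peaks, 10)
})

test_that("the known-alpha transform makes exactly M clusters spaced alpha", {
  for (M in c(3, 5)) {
    a <- 0.1
    p <- idealized_pattern(200, 200 / M, a)
    sh <- alt_shift_transform(p$pre, p$post, a)
    cl <- sort(unique(round(sh, 6)))
    expect_equal(length(cl), M)
    if (M > 1) expect_equal(unique(round(diff(cl), 6)), a)
    # alpha = 0 on unperturbed phases gives all-zero shifts
    expect_true(all(alt_shift_transform(p$pre, p$pre, 0) == 0))
  }
})

test_that("the stretch factor is recovered from phases alone", {
  set.seed(51)
  for (true_a in c(0.05, 0.10)) for (M in c(3, 5)) {
    N <- 100
    p <- idealized_pattern(N, N / M, true_a)
    ia <- infer_alpha(p$pre, p$post)
    expect_lte(abs(ia$alpha_hat - true_a), 0.005)
    idx <- sample(N, 20)
    ia20 <- infer_alpha(p$pre[idx], p$post[idx])
    expect_lte(abs(ia20$alpha_hat - true_a), 0.005)
  }
  # unperturbed input gives no stretch signal
  p <- idealized_pattern(100, 20, 0)
  expect_true(infer_alpha(p$pre, p$post)$inconclusive)
})

test_that("periodicity score calibrates on sinusoid, flat and noise", {
  expect_equal(periodicity_score(sinusoid(200, 5)), 1, tolerance = 1e-9)
  expect_equal(periodicity_score(rep(3, 200)), 0)
  set.seed(52)
  sc <- replicate(200, periodicity_score(stats::runif(200)))
  expect_lt(mean(sc), 0.2)
  expect_true(all(sc >= 0 & sc <= 1 + 1e-9))
})

test_that("subsampled DRPS converges to the full distribution", {
  set.seed(53)
  pat <- idealized_pattern(400, 40 / 3, 0.1)
  d10 <- subsample_drps_distance(pat, 10, n_draws = 8)
  d50 <- subsample_drps_distance(pat, 50, n_draws = 8)
  dall <- subsample_drps_distance(pat, 400, n_draws = 1)
  expect_gt(d10$mean_distance, d50$mean_distance)
  expect_gt(d50$mean_distance, dall$mean_distance)
  expect_equal(dall$mean_distance, 0, tolerance = 1e-12)
  expect_error(subsample_drps_distance(pat, 1), "at least 2")
})

test_that("the decision tree labels constructed perturbation series", {
  s <- c(1.2, 1.4, 1.6)
  ramp <- data.frame(strength = s, amplitude_change = c(0.05, 0.1, 0.15),
                     period_change = c(0.05, 0.12, 0.2),
                     drps_width = c(0.05, 0.11, 0.16))
  expect_equal(classify_architecture(ramp)$label, "aperiodic")
  step <- data.frame(strength = s, amplitude_change = c(0.05, 0.1, 0.15),
                     period_change = c(0.001, 0.08, 0.2),
                     drps_width = c(0.005, 0.2, 0.21))
  expect_equal(classify_architecture(step)$label, "partially_periodic")
  fully <- data.frame(strength = s, amplitude_change = c(0.05, 0.1, 0.15),
                      period_change = c(0.05, 0.12, 0.2),
                      drps_width = c(0.004, 0.01, 0.012))
  expect_equal(classify_architecture(fully)$label, "fully_periodic")
  ff <- data.frame(strength = s, amplitude_change = c(0.05, 0.1, 0.15),
                   period_change = c(0.002, 0.005, 0.008),
                   drps_width = c(0.004, 0.005, 0.006))
  expect_equal(classify_architecture(ff)$label, "feedforward")
  dead <- data.frame(strength = s, amplitude_change = c(0.001, 0.002, 0.001),
                     period_change = c(0, 0, 0), drps_width = c(0, 0, 0))
  expect_equal(classify_architecture(dead)$label,
               "perturbation_not_in_effect")
  expect_error(classify_architecture(ramp[1, , drop = FALSE]), "at least")
})

test_that("bootstrap uncertainty shrinks on concentrated spike maps", {
  set.seed(54)
  tr <- make_trajectory(240, "quasi_random", dt = 5, seed = 55)
  si <- synth_spike_map(tr, lambda = 50, r0 = 15)
  sj <- synth_spike_map(tr, lambda = 50, r0 = 15, phase = pi / 2)
  b <- bootstrap_phase_uncertainty(si$x_cm, sj$x_cm, tr, n_boot = 40,
                                   period = 50)
  expect_true(b$reliable)
  expect_lt(b$uncertainty, 0.05)
  expect_gt(b$uncertainty, 0)
  # few spikes are flagged unreliable
  b2 <- bootstrap_phase_uncertainty(si$x_cm[1:30], sj$x_cm[1:30], tr,
                                    n_boot = 10, period = 50)
  expect_false(b2$reliable)
})
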