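test_that("threshold-linear transfer rectifies", {
  expect_equal(transfer(-1), 0)
  expect_equal(transfer(0), 0)
  expect_equal(transfer(2.5), 2.5)
  expect_equal(transfer(c(-3, 0.5)), c(0, 0.5))
})

test_that("velocity modulation follows the preferred direction", {
  expect_equal(velocity_modulation(0, 1, 1), 1)
  expect_equal(velocity_modulation(0.37, 0, 1), 1)    # I cells unmodulated
  expect_equal(velocity_modulation(0.4, 1, 1), 1.4)
  expect_equal(velocity_modulation(0.4, -1, 1), 0.6)
})

test_that("total input reduces to the biases for a silent network", {
  cfg <- small_config("partially_periodic")   # no envelope: A = 1
  w <- build_weights(cfg)
  for (nm in names(w$blocks)) w$blocks[[nm]][] <- 0
  n <- cfg$N_EL + cfg$N_ER + cfg$N_I
  G <- total_input(rep(0, n), w, cfg, v = 0, mode = "multiplicative")
  expect_equal(G[1], cfg$G0 + cfg$G0p_EL)              # EL cell
  expect_equal(G[n], cfg$G0 + cfg$G0p_I)               # I cell
  Ga <- total_input(rep(0, n), w, cfg, v = 0, mode = "additive")
  expect_equal(Ga[1], cfg$W_vel + cfg$G0 + cfg$G0p_EL)
})

test_that("inhibitory-source activations lower the recurrent input", {
  cfg <- small_config("partially_periodic")
  w <- build_weights(cfg)
  n <- cfg$N_EL + cfg$N_ER + cfg$N_I
  s <- rep(0, n)
  s[(cfg$N_EL + cfg$N_ER + 1):n] <- 1      # only I cells active
  G <- total_input(s, w, cfg, v = 0, mode = "multiplicative")
  silent <- total_input(rep(0, n), w, cfg, v = 0, mode = "multiplicative")
  expect_true(all(G <= silent + 1e-12))
})

test_that("synaptic activation decays exponentially and jumps on spikes", {
  expect_equal(synapse_step(2, 0, 30, 0.5), 2 * (1 - 0.5 / 30))
  expect_equal(synapse_step(0, 1, 30, 0.5), 1)
  # after k silent steps the Euler product approaches exp(-t/tau)
  s <- 1
  for (k in 1:600) s <- synapse_step(s, 0, 30, 0.05)
  expect_equal(s, exp(-30 * 0.05 / 30 * 20), tolerance = 1e-3)
  expect_warning(synapse_step(1, 0, 1, 2), "unstable")
})

test_that("renewal spiking hits the target rate and CV", {
  set.seed(42)
  expect_equal(sum(spike_sample(0, n_steps = 1000)), 0)
  sp <- spike_sample(20, n_steps = 200000, dt = 0.5, CV = 0.5)  # 100 s
  n <- sum(sp)
  # mean count within 3 SE of rate*T (renewal SE ~ CV * sqrt(n))
  expect_lt(abs(n - 2000), 3 * 0.5 * sqrt(2000))
  isi <- diff(which(sp > 0)) * 0.5
  cv <- stats::sd(isi) / mean(isi)
  expect_gt(cv, 0.45); expect_lt(cv, 0.55)
})

test_that("trajectories are reproducible and meet the occupancy contract", {
  t1 <- make_trajectory(5, "quasi_random", dt = 0.5, seed = 3)
  t2 <- make_trajectory(5, "quasi_random", dt = 0.5, seed = 3)
  expect_identical(t1$x, t2$x)
  t0 <- make_trajectory(2, "constant_velocity", v0 = 0, dt = 0.5)
  expect_true(all(t0$x == t0$x[1]))
  # position increments equal v*dt exactly (velocity flipped pre-step)
  tq <- make_trajectory(10, "quasi_random", dt = 0.5, seed = 5)
  expect_equal(diff(tq$x), tq$v[-1] * 0.05, tolerance = 1e-9)
  # near-uniform occupancy on 1 cm bins over a 60 s run
  tr <- make_trajectory(60, "quasi_random", dt = 0.5, seed = 7)
  occ <- graphics::hist(tr$x, breaks = 0:200, plot = FALSE)$counts
  expect_lt(max(occ) / min(occ), 3)
})

test_that("simulation is deterministic and rates stay nonnegative", {
  cfg <- small_config()
  w <- build_weights(cfg)
  tr <- make_trajectory(2, "quasi_random", dt = cfg$dt, seed = 4)
  s1 <- run_lnp(cfg, w, tr, seed = 6)
  s2 <- run_lnp(cfg, w, tr, seed = 6)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$activity$frames, s2$activity$frames)
  expect_true(all(s1$activity$frames >= 0))
  expect_true(all(diff(s1$spikes$t_ms[s1$spikes$cell == s1$spikes$cell[1]])
                  >= 0))
})

test_that("a flat network fires at the transfer of its bias", {
  cfg <- small_config("partially_periodic", tau_syn = 30)
  w <- build_weights(cfg)
  for (nm in names(w$blocks)) w$blocks[[nm]][] <- 0
  tr <- make_trajectory(20, "constant_velocity", v0 = 0, dt = cfg$dt)
  sim <- run_lnp(cfg, w, tr, max_frames = 10, seed = 8)
  # expected rates: EL/ER 65 Hz, I 50 Hz
  labels <- rep(c("EL", "ER", "I"), c(cfg$N_EL, cfg$N_ER, cfg$N_I))
  for (pop in c("EL", "I")) {
    expected <- cfg$G0 + if (pop == "I") cfg$G0p_I else cfg$G0p_EL
    cells <- which(labels == pop)
    counts <- tabulate(factor(sim$spikes$cell, levels = cells),
                       nbins = length(cells))
    rate <- mean(counts) / 20
    se <- 0.5 * sqrt(sum(counts)) / length(cells) / 20
    expect_lt(abs(rate - expected), 3 * max(se, 0.1))
  }
})

test_that("synthetic spike maps recover their generating period", {
  tr <- make_trajectory(120, "quasi_random", dt = 5, seed = 12)
  sm <- synth_spike_map(tr, lambda = 50, r0 = 20)
  tc <- tuning_curve(sm$x_cm, tr)
  expect_lt(abs(tuning_period(tc) - 50), 2)
  expect_equal(tuning_amplitude(tc), 20, tolerance = 0.15)
})
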