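test_that("wrap_norm is the circular distance on a ring", {
  expect_equal(wrap_norm(3, 10), 3)
  expect_equal(wrap_norm(7, 10), 3)       # min(10 - 7, 7)
  expect_equal(wrap_norm(-7, 10), 3)      # symmetric in sign
  x <- seq(-25, 25, by = 0.5)
  expect_true(all(wrap_norm(x, 16) >= 0 & wrap_norm(x, 16) <= 8))
  expect_equal(wrap_norm(x, 16), wrap_norm(-x, 16))
  expect_error(wrap_norm(1, 0), "positive")
})

test_that("envelope is flat inside the kappa range and tapers outside", {
  expect_equal(envelope_value(50, 100, 0.3, 30), 1)
  expect_equal(envelope_value(0, 100, 0.3, 30), exp(-30 * (20 / 70)^2))
  # non-increasing in the distance from the centre beyond kappa*N
  i <- 0:50
  a <- envelope_value(i, 100, 0.3, 30)
  expect_true(all(diff(a) >= 0))          # approaching the centre
  expect_error(envelope_value(0, 100, 1.2, 30), "kappa")
})

test_that("default weight tables carry the mature-network parameters", {
  sp <- default_weight_specs()
  expect_equal(sp$I.EL$eta, 11.5); expect_equal(sp$I.EL$Delta, -2)
  expect_equal(sp$I.ER$Delta, 2); expect_equal(sp$I.EL$sigma, 4)
  expect_equal(sp$EL.I$eta, 4); expect_equal(sp$EL.I$Delta, 8)
  expect_equal(sp$EL.I$mu, -1); expect_equal(sp$EL.I$delta_cut, 3)
  expect_equal(sp$ER.I$Delta, -8); expect_equal(sp$ER.I$mu, 1)
  expect_equal(sp$I.I$eta, 12); expect_equal(sp$I.I$Delta, 4)
  expect_equal(sp$I.I$sigma, 6)
  ee <- default_weight_specs(ee_variant = TRUE)
  expect_equal(ee$I.EL$eta, 3); expect_equal(ee$EL.I$eta, 3.25)
  expect_equal(ee$I.I$eta, 4); expect_equal(ee$EL.EL$eta, 5.5)
  expect_equal(ee$EL.EL$Delta, -4); expect_equal(ee$ER.EL$Delta, 0)
})

test_that("weight blocks peak at eta/rho and honor the central cut", {
  cfg <- network_config("partially_periodic")
  w <- build_weights(cfg)
  # E->I Gaussian peak: at x_ij = rho*Delta the value is eta/rho
  B <- w$blocks$I.EL
  expect_equal(max(B), 11.5 / cfg$rho, tolerance = 1e-6)
  # I->I central cut: all entries with ||x|| < rho*delta are zero
  BII <- w$blocks$I.I
  x <- outer(seq_len(cfg$N_I), seq_len(cfg$N_I), `-`)
  expect_true(all(BII[wrap_norm(x, cfg$N_I) < 3] == 0))
  # magnitudes are nonnegative everywhere
  expect_true(all(vapply(w$blocks, function(b) all(b >= 0), logical(1))))
})

test_that("periodic blocks are translation invariant, mirror-symmetric", {
  cfg <- network_config("fully_periodic")
  w <- build_weights(cfg)
  rot <- function(M, k) M[c((k + 1):nrow(M), 1:k), c((k + 1):ncol(M), 1:k)]
  for (nm in c("I.I")) {
    B <- w$blocks[[nm]]
    expect_equal(rot(B, 5), B, tolerance = 1e-12)
  }
  # E_L -> I equals E_R -> I with both index axes reflected (Delta flip);
  # exact when source and target sizes match, so the offsets x_ij mirror
  # onto grid points
  cfe <- network_config("fully_periodic", N_EL = 40L, N_ER = 40L,
                        N_I = 40L, rho = 5)
  BL <- build_weight_block(default_weight_specs()$I.EL, cfe)
  BR <- build_weight_block(default_weight_specs()$I.ER, cfe)
  expect_equal(BL, BR[rev(seq_len(nrow(BR))), rev(seq_len(ncol(BR)))],
               tolerance = 1e-12)
})

test_that("aperiodic weights taper toward the network edge", {
  cfg <- network_config("aperiodic")
  w <- build_weights(cfg)
  B <- w$blocks$I.EL
  edge_in <- sum(abs(B[1, ])) + sum(abs(B[nrow(B), ]))
  centre_in <- sum(abs(B[nrow(B) / 2, ]))
  expect_lt(edge_in / 2, 0.15 * centre_in)
})

test_that("gain perturbation scales only inhibitory-source blocks", {
  cfg <- network_config("aperiodic")
  w <- build_weights(cfg)
  p <- apply_perturbation(w, cfg, gamma_inh = 1.33)
  expect_equal(p$weights$blocks$EL.I, 1.33 * w$blocks$EL.I)
  expect_equal(p$weights$blocks$I.I, 1.33 * w$blocks$I.I)
  expect_equal(p$weights$blocks$I.EL, w$blocks$I.EL)  # E source untouched
  # identity perturbation
  id <- apply_perturbation(w, cfg, gamma_inh = 1, tau_scale = 1)
  expect_identical(id$weights$blocks, w$blocks)
  # inverse recovers the original within float tolerance
  up <- apply_perturbation(w, cfg, gamma_inh = 2)
  back <- apply_perturbation(up$weights, up$config, gamma_inh = 0.5)
  expect_equal(back$weights$blocks$EL.I, w$blocks$EL.I, tolerance = 1e-12)
  expect_equal(back$config$tau_syn, cfg$tau_syn)
  expect_error(apply_perturbation(w, cfg, gamma_inh = -1), "positive")
})

test_that("tau perturbation rescales the synaptic time constant", {
  cfg <- network_config("aperiodic")
  w <- build_weights(cfg)
  p <- apply_perturbation(w, cfg, tau_scale = 1.5)
  expect_equal(p$config$tau_syn, 45)
  expect_identical(p$weights$blocks$I.EL, w$blocks$I.EL)
})

test_that("default configuration matches the stated population sizes", {
  cfg <- network_config("aperiodic")
  expect_equal(cfg$N_EL, 400L); expect_equal(cfg$N_ER, 400L)
  expect_equal(cfg$N_I, 160L)
  expect_equal(cfg$N_I / (cfg$N_EL + cfg$N_ER), 1 / 5)
  expect_equal(network_config("fully_periodic")$rho, 11)
  expect_equal(network_config("partially_periodic")$rho, 1)
  expect_equal(cfg$G0, 50); expect_equal(cfg$G0p_I, 0)
  expect_equal(cfg$G0p_EL, 15); expect_equal(cfg$W_vel, 200)
})
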