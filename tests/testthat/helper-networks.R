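## small networks and canned inputs shared across test files

small_config <- function(topology = "aperiodic", ...) {
  network_config(topology, N_EL = 60L, N_ER = 60L, N_I = 24L, seed = 11L,
                 ...)
}

## a pure sinusoid over L bins with k cycles
sinusoid <- function(L = 200, k = 5, phase = 0) {
  sin(2 * pi * k * (seq_len(L) - 1) / L + phase)
}

## frames matrix whose columns are identical sinusoidal population states
sinusoid_frames <- function(N = 160, cycles_in_middle_half = 4,
                            n_frames = 20) {
  lam <- (N / 2) / cycles_in_middle_half
  prof <- 10 + 5 * cos(2 * pi * (seq_len(N) - 1) / lam)
  matrix(rep(prof, n_frames), nrow = N)
}
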