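## Grid-to-place Hebbian association model: do place responses learned in
## familiar environments get spuriously triggered in novel ones?

#' Grid-to-place association model
#'
#' Multi-module grid-cell population with simplified sinusoidal tuning
#' \eqn{f_{i,m,k}(x) = \sin(2\pi x/\lambda_m + \phi_i + \tilde\phi_{m,k})}:
#' within-module phases \eqn{\phi_i = 2\pi i/N} are fixed across
#' environments while each module draws a random module-wide phase shift
#' \eqn{\tilde\phi_{m,k}} per environment. Place cells get a random
#' preferred location in each familiar environment.
#'
#' @param M_modules number of grid modules.
#' @param N grid cells per module.
#' @param lambda_m spatial periods per module (cm).
#' @param P number of place cells.
#' @param L_env number of familiar environments.
#' @param env_length environment length (cm).
#' @param seed integer seed for the random phases and place preferences.
#' @return object of class \code{grid_place_model}.
#' @export
grid_place_model <- function(M_modules = 4, N = 100,
                             lambda_m = c(30, 42, 59, 83), P = 200,
                             L_env = 2, env_length = 200, seed = 1L) {
  stopifnot(length(lambda_m) == M_modules)
  set.seed(seed)
  m <- list(M = M_modules, N = N, lambda = lambda_m, P = P, L = L_env,
            env_length = env_length,
            phi = 2 * pi * seq_len(N) / N,
            phi_tilde = matrix(stats::runif(M_modules * L_env, 0, 2 * pi),
                               M_modules, L_env),
            x_pc = matrix(stats::runif(P * L_env, 0, env_length), P, L_env))
  class(m) <- "grid_place_model"
  m
}

#' Draw the module phases of a novel environment
#'
#' @param model a \code{\link{grid_place_model}}.
#' @return vector of fresh module-wide phase shifts (radians).
#' @export
novel_environment <- function(model) stats::runif(model$M, 0, 2 * pi)

#' Grid-cell activities at positions x
#'
#' @param model a \code{\link{grid_place_model}}.
#' @param x positions (cm).
#' @param module module index.
#' @param env_phases module-wide phase shifts of the environment (vector
#'   of length \code{model$M}); a familiar environment's column of
#'   \code{model$phi_tilde} or a \code{\link{novel_environment}} draw.
#' @return matrix cells x positions of activities.
#' @export
grid_rate <- function(model, x, module, env_phases) {
  outer(model$phi, 2 * pi * x / model$lambda[module] + env_phases[module],
        function(p, th) sin(th + p))
}

#' Learn grid-to-place weights over the familiar environments
#'
#' Hebbian increments summed over environments:
#' \eqn{W_{i,j,m} = \sum_k f_{j,m,k}(x^{PC}_{i,k})} -- every place cell is
#' given a field in every familiar environment.
#'
#' @param model a \code{\link{grid_place_model}}.
#' @return array of dim (P, N, M).
#' @export
learn_weights <- function(model) {
  W <- array(0, dim = c(model$P, model$N, model$M))
  for (k in seq_len(model$L)) {
    for (m in seq_len(model$M)) {
      ## grid_rate returns cells x positions; increments are its transpose
      W[, , m] <- W[, , m] +
        t(grid_rate(model, model$x_pc[, k], m, model$phi_tilde[, k]))
    }
  }
  W
}

#' Subthreshold place-cell activation profiles
#'
#' \eqn{f^{PC}_i(x) = \sum_m \sum_j W_{i,j,m} f_{j,m,k}(x)}: the learned
#' weighted sum of grid activities, evaluated in any environment (novel
#' environments use fresh phases with the weights unchanged).
#'
#' @param model a \code{\link{grid_place_model}}.
#' @param W learned weights from \code{\link{learn_weights}}.
#' @param env_phases environment module phases.
#' @param x evaluation positions (cm); defaults to a 0.5 cm grid.
#' @return matrix P x length(x) of subthreshold activations.
#' @export
place_subthreshold <- function(model, W, env_phases,
                               x = seq(0, model$env_length, by = 0.5)) {
  act <- matrix(0, model$P, length(x))
  for (m in seq_len(model$M)) {
    F <- grid_rate(model, x, m, env_phases)      # N x |x|
    act <- act + W[, , m] %*% F
  }
  act
}

#' Familiar-field vs novel-environment activation separation
#'
#' For each place cell, compares the subthreshold activation at its field
#' location in each familiar environment with the maximal activation
#' anywhere in each of \code{n_novel} novel environments (fresh module
#' phases, weights unchanged).
#'
#' @param model a \code{\link{grid_place_model}}.
#' @param W learned weights.
#' @param n_novel number of novel environments.
#' @return list with \code{familiar} (P x L matrix of field activations),
#'   \code{novel_max} (P x n_novel matrix of per-cell maxima over
#'   position), \code{novel_values} (subsampled activations across
#'   positions in the novel environments), and summary statistics:
#'   \code{novel_median}, \code{novel_values_q95},
#'   \code{familiar_median}, \code{familiar_q05},
#'   \code{frac_novel_above_familiar} (fraction of novel positional
#'   activations exceeding the median familiar field activation) and
#'   \code{median_ratio} (per-cell min familiar field / max novel peak).
#' @export
familiar_novel_separation <- function(model, W, n_novel = 100) {
  xg <- seq(0, model$env_length, by = 0.5)
  familiar <- matrix(0, model$P, model$L)
  for (k in seq_len(model$L)) {
    act <- place_subthreshold(model, W, model$phi_tilde[, k], xg)
    idx <- vapply(model$x_pc[, k],
                  function(x0) which.min(abs(xg - x0)), integer(1))
    familiar[, k] <- act[cbind(seq_len(model$P), idx)]
  }
  novel_max <- matrix(0, model$P, n_novel)
  xs <- seq(1, length(xg), by = 8)
  novel_values <- vector("list", n_novel)
  for (r in seq_len(n_novel)) {
    act <- place_subthreshold(model, W, novel_environment(model), xg)
    novel_max[, r] <- apply(act, 1, max)
    novel_values[[r]] <- as.numeric(act[, xs])
  }
  novel_values <- unlist(novel_values)
  fam_med <- stats::median(familiar)
  ratio <- apply(familiar, 1, min) / apply(novel_max, 1, max)
  list(familiar = familiar, novel_max = novel_max,
       novel_values = novel_values,
       familiar_median = fam_med,
       familiar_q05 = stats::quantile(familiar, 0.05),
       novel_median = stats::median(novel_values),
       novel_values_q95 = stats::quantile(novel_values, 0.95),
       frac_novel_above_familiar = mean(novel_values > fam_med),
       median_ratio = stats::median(ratio))
}
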