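#' Right-hand side of the governing phase equations
#'
#' Evaluates the phase velocities of all `2N + 2M` oscillators at time `t`:
#'
#' * drivers: `dtheta_Gi = omega_Gi(t)`, `dtheta_Oi = omega_Oi(t)`;
#' * glycolysis network: `dtheta_GOi = omega_GOi(t) + (K_GO/N) * sum_j W_ij *
#'   sin(theta_GOj - theta_GOi) - eps_G * sin(theta_GOi - theta_Gi) +
#'   F_GO * r_MO * sin(Psi_MO - theta_GOi)`;
#' * OXPHOS network: as above with `K_MO`, `eps_O` and the mean field of the
#'   glycolysis network, the sign of that last term set by
#'   `config$mo_go_sign`.
#'
#' Schedule-valued couplings are evaluated at `t` (negative evaluations are
#' clamped to zero). This function exposes the same compiled kernel the
#' integrators use, mainly for testing and inspection.
#'
#' @param state a list with numeric fields `theta_G`, `theta_GO` (length `N`)
#'   and `theta_O`, `theta_MO` (length `M`): unwrapped phases, rad.
#' @param t time, seconds.
#' @param config a [model_config()].
#' @param offsets optional list with fields `G`, `GO`, `O`, `MO` of
#'   per-oscillator modulation offsets; defaults to all-zero offsets.
#' @return A list with fields `theta_G`, `theta_GO`, `theta_O`, `theta_MO`
#'   holding the phase velocities (rad/s).
#' @export
metabo_rhs <- function(state, t = 0, config = model_config(),
                       offsets = NULL) {
  stopifnot(inherits(config, "model_config"), is.list(state))
  N <- config$N
  M <- config$M
  if (length(state$theta_G) != N || length(state$theta_GO) != N ||
      length(state$theta_O) != M || length(state$theta_MO) != M) {
    stop("state dimensions do not match config (N = ", N, ", M = ", M, ")",
         call. = FALSE)
  }
  if (is.null(offsets)) {
    offsets <- list(G = rep(0, N), GO = rep(0, N),
                    O = rep(0, M), MO = rep(0, M))
  }
  stopifnot(length(offsets$G) == N, length(offsets$GO) == N,
            length(offsets$O) == M, length(offsets$MO) == M)
  y <- c(state$theta_G, state$theta_GO, state$theta_O, state$theta_MO)
  out <- rhs_cpp(t, y, N, M,
                 weight_matrix(N, config$kernel),
                 weight_matrix(M, config$kernel),
                 config$K_GO, config$K_MO,
                 sched_matrix(config$eps_G), sched_matrix(config$eps_O),
                 sched_matrix(config$F_GO), sched_matrix(config$F_MO),
                 config_fp_vector(config),
                 offsets$G, offsets$O, offsets$GO, offsets$MO,
                 if (config$mo_go_sign == "attractive") 1 else -1)
  d <- as.numeric(out$dtheta)
  list(theta_G = d[seq_len(N)],
       theta_GO = d[N + seq_len(N)],
       theta_O = d[2 * N + seq_len(M)],
       theta_MO = d[2 * N + M + seq_len(M)])
}
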