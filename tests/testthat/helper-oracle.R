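# Independent oracles used across the test files. Everything here is written
# from the model definition with plain scalar loops, deliberately sharing no
# code with the package internals.

kernel_of_distance <- function(d, kind, W) {
  switch(kind,
         linear_growth = W * d,
         harmonic_decay = W / d,
         power_decay = W^d,
         uniform = W)
}

# ring weight via the printed two-branch index formulas; the printed
# intervals are only well-defined (and symmetric) for even N
oracle_weight_branch <- function(i, j, N, kind = "linear_growth", W = 1) {
  if (i == j) return(0)
  if (i <= N / 2) {
    d <- if (j <= i + N / 2 - 1) abs(i - j) else abs(j - N - i)
  } else {
    d <- if (j >= i - N / 2 + 1) abs(i - j) else abs(j + N - i)
  }
  kernel_of_distance(d, kind, W)
}

# ring weight via the circular index separation (any N)
oracle_weight <- function(i, j, N, kind = "linear_growth", W = 1) {
  if (i == j) return(0)
  d <- min(abs(i - j), N - abs(i - j))
  kernel_of_distance(d, kind, W)
}

# naive double-loop right-hand side of the governing equations
oracle_rhs <- function(t, state, config, offsets) {
  N <- config$N
  M <- config$M
  kind <- config$kernel$kind
  W <- config$kernel$base
  epsG <- schedule_value(config$eps_G, t)
  epsO <- schedule_value(config$eps_O, t)
  FGO <- schedule_value(config$F_GO, t)
  FMO <- schedule_value(config$F_MO, t)
  wfun <- function(p, off) p$omega_mean +
    p$mod_amplitude * sin(p$mod_frequency * t + off)

  zGO <- mean(exp(1i * state$theta_GO))
  zMO <- mean(exp(1i * state$theta_MO))
  rGO <- Mod(zGO); psiGO <- Arg(zGO)
  rMO <- Mod(zMO); psiMO <- Arg(zMO)
  sgn <- if (config$mo_go_sign == "attractive") 1 else -1

  dG <- dGO <- numeric(N)
  dO <- dMO <- numeric(M)
  for (i in seq_len(N)) {
    dG[i] <- wfun(config$freq_G, offsets$G[i])
    net <- 0
    for (j in seq_len(N)) {
      net <- net + oracle_weight(i, j, N, kind, W) *
        sin(state$theta_GO[j] - state$theta_GO[i])
    }
    dGO[i] <- wfun(config$freq_GO, offsets$GO[i]) +
      (config$K_GO / N) * net -
      epsG * sin(state$theta_GO[i] - state$theta_G[i]) +
      FGO * rMO * sin(psiMO - state$theta_GO[i])
  }
  for (i in seq_len(M)) {
    dO[i] <- wfun(config$freq_O, offsets$O[i])
    net <- 0
    for (j in seq_len(M)) {
      net <- net + oracle_weight(i, j, M, kind, W) *
        sin(state$theta_MO[j] - state$theta_MO[i])
    }
    dMO[i] <- wfun(config$freq_MO, offsets$MO[i]) +
      (config$K_MO / M) * net -
      epsO * sin(state$theta_MO[i] - state$theta_O[i]) +
      sgn * FMO * rGO * sin(psiGO - state$theta_MO[i])
  }
  list(theta_G = dG, theta_GO = dGO, theta_O = dO, theta_MO = dMO)
}

# closed-form free phase under zero coupling
free_phase <- function(p, off, theta0, t) {
  if (p$mod_amplitude == 0) return(theta0 + p$omega_mean * t)
  theta0 + p$omega_mean * t - (p$mod_amplitude / p$mod_frequency) *
    (cos(p$mod_frequency * t + off) - cos(off))
}

# a small config with every coupling mode active
small_config <- function(N = 4, M = 4, seed = 1, ...) {
  model_config(N = N, M = M, F_GO = 0.11, F_MO = 0.07, seed = seed, ...)
}

# random state of matching dimensions
random_state <- function(config) {
  list(theta_G = runif(config$N, -10, 10),
       theta_GO = runif(config$N, -10, 10),
       theta_O = runif(config$M, -10, 10),
       theta_MO = runif(config$M, -10, 10))
}

random_offsets <- function(config) {
  list(G = runif(config$N, 0, 300), GO = runif(config$N, 0, 300),
       O = runif(config$M, 0, 150), MO = runif(config$M, 0, 150))
}

# brute-force phase coherence by direct phasor sum
oracle_coherence <- function(delta) Mod(mean(exp(1i * delta)))
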