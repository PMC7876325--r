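test_that("phase coherence behaves as a phasor average", {
  expect_equal(phase_coherence(rep(0.7, 100)), 1)
  # linear advance through an integer number of full cycles averages to zero
  tt <- seq(0, 100, by = 0.01)
  delta <- 2 * pi * 5 * tt / 100
  delta <- delta[-length(delta)]  # exactly 5 cycles, endpoint excluded
  expect_lt(phase_coherence(delta), 1e-10)
  # sinusoidal wobble of depth 0.3: coherence ~ |J0(0.3)| ~ 0.9776
  tt <- seq(0, 2000, by = 0.01)
  delta <- 1.1 + 0.3 * sin(2 * pi * tt / 40)
  expect_equal(phase_coherence(delta[-length(delta)]), 0.9776,
               tolerance = 1e-3)
  expect_equal(phase_coherence(delta[-length(delta)]), besselJ(0.3, 0),
               tolerance = 1e-4)
  # invariance under a constant shift; agreement with the brute-force sum
  set.seed(3)
  d <- cumsum(rnorm(500, 0, 0.05))
  expect_equal(phase_coherence(d), phase_coherence(d + 2.2),
               tolerance = 1e-12)
  expect_equal(phase_coherence(d), oracle_coherence(d), tolerance = 1e-12)
  expect_error(phase_coherence(numeric(0)), "empty")
})

test_that("boundedness is the strict 2*pi range rule", {
  expect_true(is_bounded(rep(1, 10)))
  expect_false(is_bounded(c(rep(0, 5), rep(2 * pi, 5))))  # exact slip
  tt <- seq(0, 100, 0.1)
  expect_true(is_bounded(1.5 * sin(0.3 * tt)))  # peak-to-peak 3 rad
  expect_false(is_bounded(c(0, 7)))
})

test_that("pair classification applies the 0.9 / bounded rules", {
  tt <- seq(0, 5000, 0.5)
  base <- 2 * pi * tt / 100
  # locked
  set.seed(1)
  v <- classify_pair(base + 0.8 + runif(length(tt), -0.05, 0.05), base)
  expect_equal(as.character(v$label), "permanent")
  expect_gt(v$coherence, 0.99)
  # one fast slip mid-window: still coherent, but unbounded
  slip <- 2 * pi * pmin(1, pmax(0, (tt - 2500) / 30))
  v <- classify_pair(base + 0.8 + slip, base)
  expect_equal(as.character(v$label), "intermittent")
  expect_gt(v$coherence, 0.9)
  expect_false(v$bounded)
  # constant detuning over many cycles
  v <- classify_pair(base + 0.05 * tt, base)
  expect_equal(as.character(v$label), "none")
  expect_lt(v$coherence, 0.1)
  expect_error(classify_pair(1:3, 1:4), "equal length")
})

test_that("network classification applies the 0.5 / 0.2 rules", {
  expect_equal(as.character(classify_network(rep(1, 100))$label), "permanent")
  v <- classify_network(rep(c(0.3, 0.9), 50))
  expect_equal(as.character(v$label), "intermittent")
  expect_equal(v$r_mean, 0.6)
  expect_equal(v$r_range, 0.6)
  expect_equal(as.character(classify_network(rep(0.2, 10))$label),
               "disordered")
  # boundary: mean exactly 0.5 is not synchronized
  expect_equal(as.character(classify_network(rep(0.5, 10))$label),
               "disordered")
})

test_that("pair_series builds the per-oscillator difference matrices", {
  cfg <- model_config(N = 1, M = 1, seed = 14)
  ps <- integrate_model(cfg, simulation_spec(t_total = 100, t_transient = 0,
                                             sample_interval = 0.5))
  d <- pair_series(ps, "go_g")
  expect_equal(dim(d), c(length(ps$times), 1))
  expect_equal(d[, 1], ps$theta_GO[, 1] - ps$theta_G[, 1])
  # N = 1: the inter-network mode degenerates to the oscillator pair
  dm <- pair_series(ps, "go_mo")
  expect_equal(diff(range(dm[, 1] - (ps$theta_GO[, 1] - ps$theta_MO[, 1])))
               %% (2 * pi), 0, tolerance = 1e-9)
  expect_error(pair_series(ps, "go_net"), "network-internal")
})

test_that("mean-field phase equals the common phase of an aligned network and unwraps smoothly", {
  cfg <- small_config(N = 5, M = 5, seed = 15)
  ps <- integrate_model(cfg, simulation_spec(t_total = 300, t_transient = 0,
                                             sample_interval = 0.5))
  # all MO phases replaced by one common trajectory: Psi_MO equals it
  common <- ps$theta_MO[, 1]
  ps2 <- ps
  ps2$theta_MO <- matrix(common, length(common), 5)
  d <- pair_series(ps2, "go_mo")
  # Psi_MO equals the common trajectory up to the 2*pi branch of unwrapping
  resid <- d[, 2] - (ps$theta_GO[, 2] - common)
  expect_lt(diff(range(resid)), 1e-9)
  wrapped <- resid[1] %% (2 * pi)
  expect_lt(min(wrapped, 2 * pi - wrapped), 1e-9)
  # on a smooth simulated run the unwrapped Psi has no >= pi jumps
  psi_mo <- ps$theta_GO[, 1] - pair_series(ps, "go_mo")[, 1]
  psi_go <- ps$theta_MO[, 1] - pair_series(ps, "mo_go")[, 1]
  expect_lt(max(abs(diff(psi_mo))), pi)
  expect_lt(max(abs(diff(psi_go))), pi)
})

test_that("the regime color key matches the catalogued combinations", {
  key <- regime_colors()
  expect_equal(nrow(key), 9)
  expect_setequal(
    key$color,
    c("red", "orange", "light blue", "yellow", "blue", "purple", "green",
      "cyan", "dark blue"))
  # strong-K-only row: networks permanent, every pair mode none -> purple
  lab <- tibble::tibble(go_g = "none", go_net = "permanent", go_mo = "none",
                        mo_go = "none", mo_net = "permanent", mo_o = "none")
  expect_equal(metabosc:::regime_color_of(lab), "purple")
  # mutual inter-network sync with ordered networks, no driver sync
  lab$go_mo <- lab$mo_go <- "permanent"
  expect_equal(metabosc:::regime_color_of(lab), "dark blue")
  # a combination absent from the catalogue stays unlisted
  lab$go_mo <- "intermittent"
  expect_equal(metabosc:::regime_color_of(lab), "unlisted")
})

test_that("classify_regime labels constructed runs correctly", {
  # drivers detuned from their oscillators so driver modes drift cleanly
  detuned <- list(
    freq_G = frequency_params(2 * pi / 150, 2 * pi / 600, 2 * pi / 2000),
    freq_O = frequency_params(2 * pi / 80, 2 * pi / 300, 2 * pi / 1000))
  # uncoupled: every pair mode none
  cfg <- model_config(N = 4, M = 4, K_GO = 0, K_MO = 0, eps_G = 0,
                      eps_O = 0, freq_G = detuned$freq_G,
                      freq_O = detuned$freq_O, seed = 16)
  ps <- discard_transient(
    integrate_model(cfg, simulation_spec(t_total = 3000, t_transient = 1000,
                                         sample_interval = 0.5)))
  lab <- classify_regime(ps, warn = FALSE)
  expect_equal(lab$go_g, "none")
  expect_equal(lab$mo_o, "none")
  expect_equal(lab$go_mo, "none")
  expect_equal(lab$mo_go, "none")
  # strong K, all other couplings zero: networks permanent, pairs none
  cfg2 <- model_config(N = 6, M = 6, K_GO = 0.4, K_MO = 0.4, eps_G = 0,
                       eps_O = 0, kernel = weight_kernel("uniform", 1),
                       freq_G = detuned$freq_G, freq_O = detuned$freq_O,
                       seed = 17)
  ps2 <- discard_transient(
    integrate_model(cfg2, simulation_spec(t_total = 3000, t_transient = 1000,
                                          sample_interval = 0.5)))
  lab2 <- classify_regime(ps2, warn = FALSE)
  expect_equal(lab2$go_net, "permanent")
  expect_equal(lab2$mo_net, "permanent")
  expect_equal(lab2$go_g, "none")
  expect_equal(lab2$mo_o, "none")
  expect_equal(lab2$color, "purple")
  # short windows warn
  expect_warning(classify_regime(ps2), "modulation periods")
  # determinism / idempotence
  expect_equal(tibble::as_tibble(classify_regime(ps2, warn = FALSE)),
               tibble::as_tibble(lab2))
})

test_that("majority vote breaks ties toward the weaker label", {
  expect_equal(as.character(metabosc:::majority_label(
    c("permanent", "none"))), "none")
  expect_equal(as.character(metabosc:::majority_label(
    c("permanent", "permanent", "intermittent"))), "permanent")
  expect_equal(as.character(metabosc:::majority_label(
    c("intermittent", "intermittent", "permanent", "permanent"))),
    "intermittent")
})

test_that("modified order parameter obeys its identities", {
  mk <- function(go, mo) {
    structure(list(times = 0, theta_GO = matrix(go, 1),
                   theta_MO = matrix(mo, 1)), class = "phase_series")
  }
  # fully aligned networks: s = 1
  expect_equal(modified_order(mk(rep(0.3, 4), rep(0.3, 4)))$s, 1)
  # equal-size internally aligned networks in antiphase: s = 0
  expect_equal(modified_order(mk(rep(0, 4), rep(pi, 4)))$s, 0,
               tolerance = 1e-12)
  # two-phasor identity: s = r |cos(phi / 2)| for equal r and sizes
  phi <- 1.1
  spread <- c(-0.4, 0, 0.4)  # same scatter in both networks -> same r
  go <- spread
  mo <- spread + phi
  r <- order_parameter(go)$r
  expect_equal(modified_order(mk(go, mo))$s, r * abs(cos(phi / 2)),
               tolerance = 1e-12)
  # triangle inequality on a simulated run
  cfg <- small_config(N = 5, M = 3, seed = 18)
  ps <- integrate_model(cfg, simulation_spec(t_total = 200, t_transient = 0,
                                             sample_interval = 0.5))
  s <- modified_order(ps)$s
  bound <- (5 * network_order(ps, "go")$r + 3 * network_order(ps, "mo")$r) / 8
  expect_true(all(s <= bound + 1e-12))
  expect_true(all(s >= 0 & s <= 1))
})
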