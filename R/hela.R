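#' Specification of the starved-HeLa-cell scenario
#'
#' Parameters of the time-varying simulation that emulates the glycolytic
#' oscillations of starved HeLa cells after glucose is added: 800 s of the
#' full two-network model (`N = M = 100`) in which the inter-network
#' couplings start strong (`F_GO = F_MO = 0.6`, the networks-synchronized
#' regime, producing the initial amplitude spike) and decay quadratically to
#' zero while the glucose coupling `eps_G` rises from 0.025 and flat-lines at
#' 0.7 once the glucose supply is exhausted. The quadratic coefficients
#' (`quad_A = 9.511e-7`, `quad_B = 1.931e-3`) come from a quadratic fit to
#' the measured fluorescence decay; the schedule breakpoints are 356 s and
#' 383 s. All frequency entries are angular frequencies in rad/s: mean
#' periods of about 6.7 s (glycolysis side) and 3.3 s (OXPHOS side),
#' modulation frequencies `3*pi/100` and `3*pi/50` rad/s (0.015 / 0.03 Hz —
#' the glycolysis value sits inside the 0.01-0.02 Hz band extracted from the
#' measurements), modulation amplitudes `3*pi/30` and `3*pi/15` rad/s.
#'
#' @param quad_A,quad_B quadratic / linear coefficients of the fitted ramps
#'   (per s^2, per s).
#' @param breakpoints the two schedule breakpoints, s.
#' @param t_total scenario duration, s.
#' @param N,M network sizes.
#' @param seed integer seed (initial phases and offsets).
#' @param ... further arguments passed to [model_config()] (e.g.
#'   `mo_go_sign`).
#' @return An object of class `hela_spec`.
#' @export
hela_spec <- function(quad_A = 9.511e-7, quad_B = 1.931e-3,
                      breakpoints = c(356, 383), t_total = 800,
                      N = 100, M = 100, seed = 1L, ...) {
  stopifnot(length(breakpoints) == 2L, breakpoints[1] < breakpoints[2],
            breakpoints[2] < t_total)
  structure(list(quad_A = quad_A, quad_B = quad_B,
                 breakpoints = breakpoints, t_total = t_total,
                 N = as.integer(N), M = as.integer(M),
                 seed = as.integer(seed), extra = list(...)),
            class = "hela_spec")
}

#' Coupling schedules of the HeLa scenario
#'
#' Builds the piecewise-quadratic [schedule()]s: `eps_G` follows
#' `-A*t^2 + B*t + 0.025` up to the first breakpoint and then holds at 0.7;
#' `F_GO` and `F_MO` follow `A*t^2 - B*t + 0.6` up to the second breakpoint
#' (the same polynomial continues across the first breakpoint) and are zero
#' afterwards. The decaying quadratic crosses zero just before the second
#' breakpoint, so the clamp to zero hands over continuously (within about
#' `1e-4`) to the zero segment.
#'
#' @param spec a [hela_spec()].
#' @return A list of [schedule()]s: `eps_G`, `F_GO`, `F_MO`.
#' @examples
#' sch <- hela_schedules(hela_spec())
#' schedule_value(sch$eps_G, c(0, 355.9, 400))  # 0.025, ~0.592, 0.7
#' @export
hela_schedules <- function(spec = hela_spec()) {
  stopifnot(inherits(spec, "hela_spec"))
  b1 <- spec$breakpoints[1]
  b2 <- spec$breakpoints[2]
  tt <- spec$t_total
  A <- spec$quad_A
  B <- spec$quad_B
  eps_G <- schedule(data.frame(
    t_start = c(0, b1, b2), t_end = c(b1, b2, tt),
    a = c(-A, 0, 0), b = c(B, 0, 0), c = c(0.025, 0.7, 0.7)))
  f_sched <- schedule(data.frame(
    t_start = c(0, b1, b2), t_end = c(b1, b2, tt),
    a = c(A, A, 0), b = c(-B, -B, 0), c = c(0.6, 0.6, 0)))
  list(eps_G = eps_G, F_GO = f_sched, F_MO = f_sched)
}

#' Model configuration of the HeLa scenario
#'
#' @param spec a [hela_spec()].
#' @return A [model_config()] with the HeLa frequency set and schedules.
#' @export
hela_config <- function(spec = hela_spec()) {
  stopifnot(inherits(spec, "hela_spec"))
  sch <- hela_schedules(spec)
  args <- c(list(
    N = spec$N, M = spec$M,
    K_GO = 0.025, K_MO = 0.025,
    eps_G = sch$eps_G, eps_O = 0.025,
    F_GO = sch$F_GO, F_MO = sch$F_MO,
    freq_G = frequency_params(3 * pi / 10, 3 * pi / 30, 3 * pi / 100),
    freq_GO = frequency_params(3 * pi / 10, 3 * pi / 30, 3 * pi / 100),
    freq_O = frequency_params(3 * pi / 5, 3 * pi / 15, 3 * pi / 50),
    freq_MO = frequency_params(3 * pi / 5, 3 * pi / 15, 3 * pi / 50),
    seed = spec$seed), spec$extra)
  do.call(model_config, args)
}

#' Run the HeLa scenario
#'
#' Integrates the time-varying scenario with the fixed-step RK4 scheme over
#' the full 800 s (no transient discard: the initial spike is part of the
#' output) and returns the modified two-network order parameter `s(t)`, the
#' model output comparable to the measured single-cell NADH fluorescence.
#'
#' @param spec a [hela_spec()].
#' @param sim a [simulation_spec()] with `integrator = "rk4"`; defaults to
#'   the scenario protocol (800 s, 0.01 s steps, 0.1 s sampling).
#' @param keep_series also attach the full `phase_series` as an attribute.
#' @return A tibble of class `hela_series` with columns `time`, `s`, `r_go`,
#'   `r_mo`, carrying `spec` (and optionally the series) as attributes.
#' @export
run_hela <- function(spec = hela_spec(),
                     sim = simulation_spec(t_total = spec$t_total,
                                           t_transient = 0,
                                           sample_interval = 0.1,
                                           integrator = "rk4",
                                           rk4_step = 0.01,
                                           seed = spec$seed),
                     keep_series = FALSE) {
  stopifnot(inherits(spec, "hela_spec"))
  if (sim$integrator != "rk4") {
    stop("the HeLa scenario uses the fixed-step rk4 integrator",
         call. = FALSE)
  }
  config <- hela_config(spec)
  series <- integrate_model(config, sim)
  s <- modified_order(series)
  out <- tibble::tibble(
    time = s$time, s = s$s,
    r_go = network_order(series, "go")$r,
    r_mo = network_order(series, "mo")$r
  )
  attr(out, "spec") <- spec
  if (keep_series) attr(out, "series") <- series
  class(out) <- c("hela_series", class(out))
  out
}

#' @rdname run_hela
#' @param x a `hela_series`.
#' @param ... unused.
#' @export
glance.hela_series <- function(x, ...) {
  tibble::tibble(
    t_total = x$time[nrow(x)],
    s_mean_early = mean(x$s[x$time >= 50 & x$time <= 300]),
    s_mean_late = mean(x$s[x$time >= 600 & x$time <= 800]),
    s_min = min(x$s), s_max = max(x$s),
    seed = attr(x, "spec")$seed
  )
}
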