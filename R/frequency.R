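#' Non-autonomous natural-frequency parameters
#'
#' Each oscillator of element `X` (glucose, oxygen, glycolysis, OXPHOS)
#' carries a sinusoidally modulated natural frequency
#' `omega_X(t) = omega + A * sin(omega_m * t + t_i)`, where `t_i` is a fixed
#' per-oscillator offset. `omega` is the mean angular frequency (rad/s), `A`
#' the modulation amplitude (rad/s) and `omega_m` the modulation angular
#' frequency (rad/s).
#'
#' @param omega_mean mean angular frequency, rad/s; must be positive.
#' @param mod_amplitude modulation amplitude `A`, rad/s; non-negative.
#' @param mod_frequency modulation angular frequency `omega_m`, rad/s; must
#'   be positive whenever `mod_amplitude > 0`.
#' @return An object of class `frequency_params`.
#' @examples
#' frequency_params(2 * pi / 200, 2 * pi / 600, 2 * pi / 2000)
#' @export
frequency_params <- function(omega_mean, mod_amplitude = 0,
                             mod_frequency = 0) {
  stopifnot(is.numeric(omega_mean), length(omega_mean) == 1L, omega_mean > 0,
            is.numeric(mod_amplitude), length(mod_amplitude) == 1L,
            mod_amplitude >= 0,
            is.numeric(mod_frequency), length(mod_frequency) == 1L,
            mod_frequency >= 0)
  if (mod_amplitude > 0 && mod_frequency <= 0) {
    stop("mod_frequency must be > 0 when mod_amplitude > 0", call. = FALSE)
  }
  structure(list(omega_mean = omega_mean, mod_amplitude = mod_amplitude,
                 mod_frequency = mod_frequency),
            class = "frequency_params")
}

#' @export
print.frequency_params <- function(x, ...) {
  cat("<frequency_params> omega =", format(x$omega_mean),
      "A =", format(x$mod_amplitude), "omega_m =", format(x$mod_frequency),
      "rad/s\n")
  invisible(x)
}

#' Sample per-oscillator modulation offsets
#'
#' Draws the fixed offsets `t_i` that desynchronise the frequency modulation
#' across the oscillators of one element. In the default `"time"` mode each
#' offset is uniform on `[0, 1/omega_m]` (added directly inside the
#' modulation sine, as the model defines); note this range spans less than
#' one radian of modulation phase. The alternative `"phase"` mode draws a
#' full-cycle uniform offset on `[0, 2*pi)`.
#'
#' Offsets are drawn from the session RNG, so results are reproducible after
#' `set.seed()`.
#'
#' @param params a [frequency_params()].
#' @param count number of oscillators.
#' @param mode `"time"` (default) or `"phase"`.
#' @return Numeric vector of `count` offsets. When `mod_amplitude` is zero
#'   the offsets are irrelevant and all-zero offsets are returned.
#' @export
sample_offsets <- function(params, count, mode = c("time", "phase")) {
  stopifnot(inherits(params, "frequency_params"),
            length(count) == 1L, count >= 1)
  mode <- match.arg(mode)
  if (params$mod_amplitude == 0) {
    return(rep(0, count))
  }
  if (params$mod_frequency <= 0) {
    stop("cannot sample offsets: mod_frequency is 0 with mod_amplitude > 0",
         call. = FALSE)
  }
  upper <- if (mode == "time") 1 / params$mod_frequency else 2 * pi
  runif(count, 0, upper)
}

#' Instantaneous natural frequency
#'
#' Evaluates `omega + A * sin(omega_m * t + offset)`, the time-varying
#' natural frequency of one oscillator; bounded in
#' `[omega - A, omega + A]`.
#'
#' @param t time(s), seconds.
#' @param params a [frequency_params()].
#' @param offset the oscillator's fixed modulation offset `t_i`.
#' @return Angular frequency (rad/s), vectorised over `t` and `offset`.
#' @export
instantaneous_frequency <- function(t, params, offset = 0) {
  stopifnot(inherits(params, "frequency_params"))
  params$omega_mean +
    params$mod_amplitude * sin(params$mod_frequency * t + offset)
}
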