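#' Model configuration for the two-network metabolism model
#'
#' Collects every structural and coupling parameter of the model: two
#' weighted all-to-all ring networks of non-autonomous Kuramoto phase
#' oscillators (glycolysis, size `N`; OXPHOS, size `M`), each oscillator
#' driven by its own supply oscillator (glucose, oxygen) and each network
#' coupled to the mean field of the other. Defaults reproduce the reference
#' parameter set of the weighted-network simulations (couplings 0.025,
#' glycolysis-side period 200 s, OXPHOS-side period 100 s, modulation periods
#' 2000/1000 s, modulation amplitudes `2*pi/600` and `2*pi/300`, `N = M =
#' 100`, `W = 1`) with the inter-network couplings `F_GO`, `F_MO` at zero.
#'
#' The driver couplings `eps_G`, `eps_O` and the inter-network couplings
#' `F_GO`, `F_MO` may each be a non-negative scalar or a [schedule()].
#'
#' `mo_go_sign` selects the sign of the OXPHOS-side mean-field term. The
#' governing equations as printed subtract the whole `F_MO * r_GO *
#' sin(Psi_GO - theta_MOi)` term (`"repulsive"`), which contradicts the
#' individual-oscillator model this one extends, where every coupling term is
#' attractive; `"attractive"` (the default) restores that convention. See the
#' methods vignette for the full argument.
#'
#' @param N,M numbers of glycolysis and OXPHOS oscillators (each also the
#'   number of corresponding drivers).
#' @param K_GO,K_MO intra-network coupling strengths, rad/s.
#' @param eps_G,eps_O driver coupling strengths, rad/s; scalar or [schedule()].
#' @param F_GO,F_MO inter-network (mean-field) coupling strengths, rad/s;
#'   scalar or [schedule()].
#' @param kernel a [weight_kernel()] for the ring weighting.
#' @param freq_G,freq_O,freq_GO,freq_MO [frequency_params()] per element.
#' @param noise_sigma scaling of optional additive white frequency noise on
#'   the network oscillators, rad/s^(1/2); requires the fixed-step
#'   integrator when positive.
#' @param seed integer seed controlling modulation offsets and initial
#'   phases.
#' @param mo_go_sign `"attractive"` or `"repulsive"` (see Details).
#' @param offset_mode offset sampling mode, see [sample_offsets()].
#' @return An object of class `model_config`.
#' @export
model_config <- function(N = 100, M = 100,
                         K_GO = 0.025, K_MO = 0.025,
                         eps_G = 0.025, eps_O = 0.025,
                         F_GO = 0, F_MO = 0,
                         kernel = weight_kernel("linear_growth", 1),
                         freq_G = frequency_params(2 * pi / 200, 2 * pi / 600,
                                                   2 * pi / 2000),
                         freq_O = frequency_params(2 * pi / 100, 2 * pi / 300,
                                                   2 * pi / 1000),
                         freq_GO = frequency_params(2 * pi / 200, 2 * pi / 600,
                                                    2 * pi / 2000),
                         freq_MO = frequency_params(2 * pi / 100, 2 * pi / 300,
                                                    2 * pi / 1000),
                         noise_sigma = 0, seed = 1L,
                         mo_go_sign = c("attractive", "repulsive"),
                         offset_mode = c("time", "phase")) {
  mo_go_sign <- match.arg(mo_go_sign)
  offset_mode <- match.arg(offset_mode)
  stopifnot(N >= 1, M >= 1, K_GO >= 0, K_MO >= 0, noise_sigma >= 0,
            inherits(kernel, "weight_kernel"),
            inherits(freq_G, "frequency_params"),
            inherits(freq_O, "frequency_params"),
            inherits(freq_GO, "frequency_params"),
            inherits(freq_MO, "frequency_params"))
  for (nm in c("eps_G", "eps_O", "F_GO", "F_MO")) {
    x <- get(nm)
    if (is_schedule(x)) next
    if (!(is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0)) {
      stop(nm, " must be a non-negative scalar or a schedule", call. = FALSE)
    }
  }
  structure(list(N = as.integer(N), M = as.integer(M),
                 K_GO = K_GO, K_MO = K_MO,
                 eps_G = eps_G, eps_O = eps_O, F_GO = F_GO, F_MO = F_MO,
                 kernel = kernel,
                 freq_G = freq_G, freq_O = freq_O,
                 freq_GO = freq_GO, freq_MO = freq_MO,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 mo_go_sign = mo_go_sign, offset_mode = offset_mode),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  fmt_c <- function(v) if (is_schedule(v)) {
    paste0("schedule[", nrow(v), " seg]")
  } else format(v)
  cat("<model_config>\n")
  cat("  N =", x$N, " M =", x$M, "\n")
  cat("  K_GO =", format(x$K_GO), " K_MO =", format(x$K_MO), "\n")
  cat("  eps_G =", fmt_c(x$eps_G), " eps_O =", fmt_c(x$eps_O), "\n")
  cat("  F_GO =", fmt_c(x$F_GO), " F_MO =", fmt_c(x$F_MO), "\n")
  cat("  kernel:", x$kernel$kind, "(W =", format(x$kernel$base), ")\n")
  cat("  noise_sigma =", format(x$noise_sigma), " seed =", x$seed,
      " mo_go_sign =", x$mo_go_sign, "\n")
  invisible(x)
}

#' Reference parameter preset of the network simulations
#'
#' The parameter set used for the weighted-network regime-map simulations:
#' all fixed couplings at 0.025, glycolysis-side mean period 200 s and
#' OXPHOS-side 100 s, modulation periods 2000 s / 1000 s, modulation
#' amplitudes `2*pi/600` / `2*pi/300` rad/s, `N = M = 100` and a harmonic
#' ring kernel with `W = 1`. The inter-network couplings default to zero;
#' sweeps set them per cell over `[0, 0.3]`.
#'
#' @param F_GO,F_MO inter-network couplings, rad/s.
#' @param N,M network sizes.
#' @param ... further arguments passed to [model_config()].
#' @return A [model_config()].
#' @export
preset_table_network <- function(F_GO = 0, F_MO = 0, N = 100, M = 100, ...) {
  model_config(N = N, M = M, F_GO = F_GO, F_MO = F_MO, ...)
}

config_fp_vector <- function(config) {
  f <- function(p) c(p$omega_mean, p$mod_amplitude, p$mod_frequency)
  c(f(config$freq_G), f(config$freq_O), f(config$freq_GO), f(config$freq_MO))
}

# draw modulation offsets and initial phases from the config seed, in a
# fixed documented order: offsets G, GO, O, MO, then initial phases for the
# full state [G, GO, O, MO]
draw_initial_conditions <- function(config) {
  set.seed(config$seed)
  offsets <- list(
    G  = sample_offsets(config$freq_G, config$N, config$offset_mode),
    GO = sample_offsets(config$freq_GO, config$N, config$offset_mode),
    O  = sample_offsets(config$freq_O, config$M, config$offset_mode),
    MO = sample_offsets(config$freq_MO, config$M, config$offset_mode)
  )
  theta0 <- runif(2 * config$N + 2 * config$M, 0, 2 * pi)
  list(offsets = offsets, theta0 = theta0)
}

coupling_to_json <- function(x) {
  if (is_schedule(x)) list(segments = as.data.frame(unclass(x)[
    c("t_start", "t_end", "a", "b", "c")])) else x
}

coupling_from_json <- function(x) {
  if (is.list(x) && !is.null(x$segments)) {
    seg <- as.data.frame(x$segments)
    seg$t_end[!is.finite(seg$t_end) | seg$t_end > 1e300] <- Inf
    schedule(seg)
  } else {
    as.numeric(x)
  }
}

#' Write a model configuration to JSON
#'
#' Serialises a [model_config()] to a JSON document whose keys follow the
#' model symbols (`N`, `M`, `K_GO`, `K_MO`, `eps_G`, `eps_O`, `F_GO`,
#' `F_MO`, `W`, `kernel`, `omega_*`, `A_*`, `omega_*m`, `sigma`, `seed`).
#' Schedule-valued couplings are stored as segment lists.
#'
#' @param config a [model_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "model_config"))
  doc <- list(
    N = config$N, M = config$M,
    K_GO = config$K_GO, K_MO = config$K_MO,
    eps_G = coupling_to_json(config$eps_G),
    eps_O = coupling_to_json(config$eps_O),
    F_GO = coupling_to_json(config$F_GO),
    F_MO = coupling_to_json(config$F_MO),
    W = config$kernel$base, kernel = config$kernel$kind,
    omega_G = config$freq_G$omega_mean, A_G = config$freq_G$mod_amplitude,
    omega_Gm = config$freq_G$mod_frequency,
    omega_O = config$freq_O$omega_mean, A_O = config$freq_O$mod_amplitude,
    omega_Om = config$freq_O$mod_frequency,
    omega_GO = config$freq_GO$omega_mean, A_GO = config$freq_GO$mod_amplitude,
    omega_GOm = config$freq_GO$mod_frequency,
    omega_MO = config$freq_MO$omega_mean, A_MO = config$freq_MO$mod_amplitude,
    omega_MOm = config$freq_MO$mod_frequency,
    sigma = config$noise_sigma, seed = config$seed,
    mo_go_sign = config$mo_go_sign, offset_mode = config$offset_mode
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a model configuration from JSON
#'
#' @param path a JSON file written by [write_config()].
#' @return A [model_config()].
#' @export
read_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_config(
    N = doc$N, M = doc$M, K_GO = doc$K_GO, K_MO = doc$K_MO,
    eps_G = coupling_from_json(doc$eps_G),
    eps_O = coupling_from_json(doc$eps_O),
    F_GO = coupling_from_json(doc$F_GO),
    F_MO = coupling_from_json(doc$F_MO),
    kernel = weight_kernel(doc$kernel, doc$W),
    freq_G = frequency_params(doc$omega_G, doc$A_G, doc$omega_Gm),
    freq_O = frequency_params(doc$omega_O, doc$A_O, doc$omega_Om),
    freq_GO = frequency_params(doc$omega_GO, doc$A_GO, doc$omega_GOm),
    freq_MO = frequency_params(doc$omega_MO, doc$A_MO, doc$omega_MOm),
    noise_sigma = doc$sigma, seed = doc$seed,
    mo_go_sign = doc$mo_go_sign, offset_mode = doc$offset_mode
  )
}
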