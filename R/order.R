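#' Kuramoto order parameter
#'
#' The modulus `r` and argument `Psi` of the mean unit phasor
#' `r * exp(i * Psi) = mean(exp(i * theta))`. `r = 1` indicates a totally
#' ordered population (all oscillators at the same phase), `r ~ 0` a
#' disordered one. `r` is invariant under adding a common constant to all
#' phases.
#'
#' @param phases numeric vector of phases (rad), or a matrix with one row per
#'   time sample and one column per oscillator.
#' @return For a vector, a one-row tibble with columns `r` and `psi`; for a
#'   matrix, one row per time sample.
#' @examples
#' order_parameter(c(0, pi / 2)) # r = sqrt(2)/2, psi = pi/4
#' @export
order_parameter <- function(phases) {
  if (is.matrix(phases)) {
    if (ncol(phases) < 1L) stop("empty phase matrix", call. = FALSE)
    z_re <- rowMeans(cos(phases))
    z_im <- rowMeans(sin(phases))
  } else {
    if (length(phases) < 1L) stop("empty phase vector", call. = FALSE)
    z_re <- mean(cos(phases))
    z_im <- mean(sin(phases))
  }
  tibble::tibble(r = sqrt(z_re^2 + z_im^2), psi = atan2(z_im, z_re))
}

#' Order-parameter time series of one network
#'
#' @param series a [phase_series][integrate_model()].
#' @param network `"go"` (glycolysis) or `"mo"` (OXPHOS).
#' @return A tibble with columns `time`, `r`, `psi` (psi wrapped to
#'   `(-pi, pi]`).
#' @export
network_order <- function(series, network = c("go", "mo")) {
  stopifnot(inherits(series, "phase_series"))
  network <- match.arg(network)
  th <- if (network == "go") series$theta_GO else series$theta_MO
  op <- order_parameter(th)
  tibble::tibble(time = series$times, r = op$r, psi = op$psi)
}

#' Modified two-network order parameter
#'
#' The joint order parameter
#' `s(t) = |sum(exp(i * theta_GO)) + sum(exp(i * theta_MO))| / (N + M)`,
#' which reads as the collective amplitude of the two metabolic networks
#' together: it is 1 only when both networks are internally ordered *and*
#' aligned with each other, and it vanishes when two equally sized ordered
#' networks sit in antiphase. Comparable to single-cell NADH fluorescence,
#' which is maximal when glycolysis and OXPHOS act coherently.
#'
#' @param series a [phase_series][integrate_model()].
#' @return A tibble with columns `time` and `s` (`s` in `[0, 1]`).
#' @export
modified_order <- function(series) {
  stopifnot(inherits(series, "phase_series"))
  N <- ncol(series$theta_GO)
  M <- ncol(series$theta_MO)
  z_re <- rowSums(cos(series$theta_GO)) + rowSums(cos(series$theta_MO))
  z_im <- rowSums(sin(series$theta_GO)) + rowSums(sin(series$theta_MO))
  tibble::tibble(time = series$times,
                 s = sqrt(z_re^2 + z_im^2) / (N + M))
}

# unwrap a phase series: remove artificial 2*pi jumps between samples
unwrap_phase <- function(x) {
  if (length(x) < 2L) return(x)
  d <- diff(x)
  x + c(0, -2 * pi * cumsum(round(d / (2 * pi))))
}
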