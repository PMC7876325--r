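#' Phase coherence of a phase-difference series
#'
#' The modulus of the time-averaged unit phasor of the phase difference,
#' `sqrt(mean(cos(delta))^2 + mean(sin(delta))^2)`: 1 for a constant
#' difference, near 0 for a steadily drifting one. Invariant under adding a
#' constant to the whole series.
#'
#' @param delta numeric phase-difference series, rad (analysis window only).
#' @return Coherence in `[0, 1]`.
#' @export
phase_coherence <- function(delta) {
  if (length(delta) < 1L) stop("empty phase-difference series", call. = FALSE)
  sqrt(mean(cos(delta))^2 + mean(sin(delta))^2)
}

#' Is a phase difference bounded within a 2*pi band?
#'
#' `TRUE` iff `max(delta) - min(delta) < 2*pi` over the window, i.e. the
#' difference never completes a full slip. A single exact 2*pi step already
#' counts as unbounded.
#'
#' @param delta numeric phase-difference series, rad (full analysis window).
#' @return Logical.
#' @export
is_bounded <- function(delta) {
  if (length(delta) < 1L) stop("empty phase-difference series", call. = FALSE)
  (max(delta) - min(delta)) < 2 * pi
}

pair_label_levels <- c("none", "intermittent", "permanent")
network_label_levels <- c("disordered", "intermittent", "permanent")

#' Classify the synchronization of an oscillator pair
#'
#' Applies the finite-time criteria to `delta = a - b`: coherence above 0.9
#' with the difference bounded within 2*pi over the whole window is
#' *permanent* synchronization; coherence above 0.9 with an unbounded
#' difference (episodic slips) is *intermittent*; anything else is *none*.
#'
#' @param a,b equal-length unwrapped phase series, rad, on the analysis
#'   window.
#' @param coherence_threshold coherence threshold (default 0.9).
#' @return A one-row tibble with columns `coherence`, `bounded`, `label`.
#' @export
classify_pair <- function(a, b, coherence_threshold = 0.9) {
  if (length(a) != length(b)) {
    stop("phase series must have equal length", call. = FALSE)
  }
  delta <- a - b
  coh <- phase_coherence(delta)
  bnd <- is_bounded(delta)
  label <- if (coh > coherence_threshold) {
    if (bnd) "permanent" else "intermittent"
  } else "none"
  tibble::tibble(coherence = coh, bounded = bnd,
                 label = factor(label, levels = pair_label_levels))
}

#' Classify the synchronization of a network
#'
#' A network is synchronized when its time-averaged Kuramoto order parameter
#' exceeds 0.5 (more ordered than disordered); the synchronization is
#' *permanent* when the order parameter varies by less than 0.2 over the
#' window (`max - min`), *intermittent* otherwise. A non-autonomous network's
#' order parameter naturally breathes with the frequency modulation, so only
#' variation above 0.2 is attributed to intermittency or disorder.
#'
#' @param r_series order-parameter time series over the analysis window.
#' @param mean_threshold,range_threshold the 0.5 / 0.2 thresholds.
#' @return A one-row tibble with columns `r_mean`, `r_range`, `label`.
#' @export
classify_network <- function(r_series, mean_threshold = 0.5,
                             range_threshold = 0.2) {
  if (length(r_series) < 1L) stop("empty order-parameter series",
                                  call. = FALSE)
  r_mean <- mean(r_series)
  r_range <- max(r_series) - min(r_series)
  label <- if (r_mean > mean_threshold) {
    if (r_range < range_threshold) "permanent" else "intermittent"
  } else "disordered"
  tibble::tibble(r_mean = r_mean, r_range = r_range,
                 label = factor(label, levels = network_label_levels))
}

#' Per-oscillator phase-difference series for one synchronization mode
#'
#' Driver modes give the per-oscillator differences to the corresponding
#' supply oscillator (`go_g`: `theta_GOi - theta_Gi`; `mo_o`:
#' `theta_MOi - theta_Oi`). Inter-network modes give the differences to the
#' mean-field phase of the other network (`go_mo`: `theta_GOi - Psi_MO`;
#' `mo_go`: `theta_MOi - Psi_GO`), with `Psi` computed per sample and
#' unwrapped over time so boundedness stays meaningful; samples where the
#' other network's order parameter falls below `1e-6` carry the previous
#' `Psi` (the argument is undefined at `r = 0`).
#'
#' @param series a [phase_series][integrate_model()] (transient already
#'   discarded).
#' @param mode one of `"go_g"`, `"mo_o"`, `"go_mo"`, `"mo_go"`.
#' @return A matrix of phase differences, one row per sample and one column
#'   per oscillator, with the sample times in `attr(, "times")`.
#' @export
pair_series <- function(series, mode = c("go_g", "mo_o", "go_mo", "mo_go")) {
  stopifnot(inherits(series, "phase_series"))
  mode <- tryCatch(match.arg(mode), error = function(e) {
    stop("mode must be a driver or inter-network mode ",
         "(network-internal modes use classify_network)", call. = FALSE)
  })
  delta <- switch(mode,
    go_g = series$theta_GO - series$theta_G,
    mo_o = series$theta_MO - series$theta_O,
    go_mo = series$theta_GO - mean_field_phase(series$theta_MO),
    mo_go = series$theta_MO - mean_field_phase(series$theta_GO)
  )
  attr(delta, "times") <- series$times
  delta
}

# unwrapped mean-field phase Psi(t) of a phase matrix (rows = samples)
mean_field_phase <- function(theta, r_floor = 1e-6) {
  z_re <- rowMeans(cos(theta))
  z_im <- rowMeans(sin(theta))
  r <- sqrt(z_re^2 + z_im^2)
  psi <- atan2(z_im, z_re)
  low <- which(r < r_floor)
  for (k in low) if (k > 1L) psi[k] <- psi[k - 1L]
  unwrap_phase(psi)
}

# majority label across per-oscillator verdicts; ties break toward the
# weaker label (none < intermittent < permanent)
majority_label <- function(labels, levels = pair_label_levels) {
  counts <- table(factor(labels, levels = levels))
  winners <- names(counts)[counts == max(counts)]
  factor(winners[1], levels = levels)  # levels are ordered weakest first
}

#' Synchronization-regime color key
#'
#' The catalogue of six-mode regime combinations observed for the network
#' models, each assigned a color used in the regime maps. Combinations not in
#' the catalogue are reported as `"unlisted"`, never forced into a listed
#' color.
#'
#' @return A tibble with columns `color`, `go_g`, `go_net`, `go_mo`,
#'   `mo_go`, `mo_net`, `mo_o`.
#' @export
regime_colors <- function() {
  tibble::tribble(
    ~color,       ~go_g,       ~go_net,        ~go_mo,      ~mo_go,      ~mo_net,        ~mo_o,
    "red",        "permanent", "permanent",    "none",      "none",      "permanent",    "permanent",
    "orange",     "none",      "permanent",    "none",      "none",      "permanent",    "permanent",
    "light blue", "none",      "permanent",    "permanent", "permanent", "permanent",    "permanent",
    "yellow",     "permanent", "permanent",    "none",      "none",      "permanent",    "none",
    "blue",       "permanent", "permanent",    "permanent", "permanent", "permanent",    "none",
    "purple",     "none",      "permanent",    "none",      "none",      "permanent",    "none",
    "green",      "none",      "permanent",    "none",      "none",      "intermittent", "none",
    "cyan",       "none",      "intermittent", "none",      "none",      "permanent",    "none",
    "dark blue",  "none",      "permanent",    "permanent", "permanent", "permanent",    "none"
  )
}

regime_color_of <- function(labels) {
  key <- regime_colors()
  hit <- key$go_g == labels$go_g & key$go_net == labels$go_net &
    key$go_mo == labels$go_mo & key$mo_go == labels$mo_go &
    key$mo_net == labels$mo_net & key$mo_o == labels$mo_o
  if (any(hit)) key$color[which(hit)[1]] else "unlisted"
}

#' Classify a run into the six-mode synchronization regime
#'
#' Evaluates all six synchronization modes of the model on a transient-free
#' phase series: the two driver modes (`go_g`, `mo_o`) and the two
#' inter-network modes (`go_mo`, `mo_go`) via per-oscillator pair
#' classification with a majority vote (ties break toward the weaker label),
#' and the two network-internal modes (`go_net`, `mo_net`) via the
#' order-parameter rules. The six labels are then mapped to the regime color
#' key (see [regime_colors()]).
#'
#' @param series a [phase_series][integrate_model()] with the transient
#'   already discarded.
#' @param warn warn when the analysis window is shorter than 10 modulation
#'   periods (classification can be unstable on short windows).
#' @return A one-row tibble with character columns `go_g`, `go_net`,
#'   `go_mo`, `mo_go`, `mo_net`, `mo_o` and `color`; per-mode details (pair
#'   coherences, order-parameter statistics) in `attr(, "detail")`.
#' @export
classify_regime <- function(series, warn = TRUE) {
  stopifnot(inherits(series, "phase_series"))
  if (warn) {
    window <- series$times[length(series$times)] - series$times[1]
    om <- c(series$config$freq_G$mod_frequency,
            series$config$freq_O$mod_frequency,
            series$config$freq_GO$mod_frequency,
            series$config$freq_MO$mod_frequency)
    om <- om[om > 0]
    if (length(om) > 0 && window < 10 * (2 * pi / min(om))) {
      warning("analysis window shorter than 10 modulation periods; ",
              "classification may be unstable", call. = FALSE)
    }
  }

  pair_mode <- function(mode) {
    delta <- pair_series(series, mode)
    verdicts <- purrr::map_dfr(seq_len(ncol(delta)), function(j) {
      d <- delta[, j]
      coh <- phase_coherence(d)
      bnd <- is_bounded(d)
      tibble::tibble(
        oscillator = j, coherence = coh, bounded = bnd,
        label = if (coh > 0.9) {
          if (bnd) "permanent" else "intermittent"
        } else "none")
    })
    verdicts
  }

  detail <- list()
  labels <- list()
  for (mode in c("go_g", "mo_o", "go_mo", "mo_go")) {
    v <- pair_mode(mode)
    detail[[mode]] <- v
    labels[[mode]] <- as.character(majority_label(v$label))
  }
  for (net in c("go", "mo")) {
    r <- network_order(series, net)$r
    v <- classify_network(r)
    detail[[paste0(net, "_net")]] <- v
    labels[[paste0(net, "_net")]] <- as.character(v$label)
  }

  out <- tibble::tibble(
    go_g = labels$go_g, go_net = labels$go_net, go_mo = labels$go_mo,
    mo_go = labels$mo_go, mo_net = labels$mo_net, mo_o = labels$mo_o
  )
  out$color <- regime_color_of(out)
  attr(out, "detail") <- detail
  class(out) <- c("regime_label", class(out))
  out
}

#' Write a regime verdict to JSON
#'
#' One object per run: the six mode labels, the color, per-pair coherences
#' and the network order-parameter statistics.
#'
#' @param label a [classify_regime()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_regime_label <- function(label, path) {
  stopifnot(inherits(label, "regime_label"))
  detail <- attr(label, "detail")
  doc <- c(as.list(tibble::as_tibble(label)[1, ]),
           list(detail = detail))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
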