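#' Specification of a labelled synthetic fixture
#'
#' Fixtures are synthetic phase series with a known ground-truth
#' synchronization label, used to validate the metrics and classifiers
#' without running the full model. Pair kinds (`"locked"`, `"drifting"`,
#' `"slipping"`) produce two phase series whose difference realises the
#' label; network kinds (`"ordered_network"`, `"disordered_network"`,
#' `"intermittent_network"`) produce a phase matrix whose order-parameter
#' series realises it. Generation is fully determined by `seed`.
#'
#' Kind-specific parameters (all optional, with labelled-by-construction
#' defaults):
#' * `locked`: `offset` (constant difference, rad), `jitter` (half-width of
#'   the iid bounded jitter, rad; default 0.05);
#' * `drifting`: `detuning` (rad/s; default 0.05, ~40 cycles over the default
#'   window);
#' * `slipping`: `n_slips` (default 3), `slip_duration` (s each, default 40),
#'   plus the locked parameters;
#' * `ordered_network`: `n_osc` (default 100), `spread` (circular s.d. of the
#'   fixed phase scatter, rad; default 0.3, giving r ~ exp(-0.3^2/2) ~ 0.956);
#' * `disordered_network`: `n_osc` (default 100; phases redrawn uniformly at
#'   every sample, r_mean ~ sqrt(pi)/(2*sqrt(n)));
#' * `intermittent_network`: `n_osc`, `spread_low` (0.3), `spread_high`
#'   (1.5), `alternation` (block length, s; default 250), alternating order
#'   levels r ~ 0.956 / 0.325.
#'
#' @param kind fixture kind (see above).
#' @param duration window length, s.
#' @param sample_interval sampling interval, s.
#' @param seed integer seed.
#' @param ... kind-specific parameters.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(kind = c("locked", "drifting", "slipping",
                                  "ordered_network", "disordered_network",
                                  "intermittent_network"),
                         duration = 5000, sample_interval = 0.5,
                         seed = 1L, ...) {
  kind <- match.arg(kind)
  stopifnot(duration > 0, sample_interval > 0)
  pars <- list(...)
  structure(list(kind = kind, duration = duration,
                 sample_interval = sample_interval, seed = as.integer(seed),
                 pars = pars),
            class = "fixture_spec")
}

fixture_par <- function(spec, name, default) {
  if (!is.null(spec$pars[[name]])) spec$pars[[name]] else default
}

#' Generate a labelled oscillator-pair fixture
#'
#' Builds two phase series `a`, `b` whose difference realises the requested
#' pair label: `locked` is a constant difference plus small bounded iid
#' jitter (coherence > 0.99, bounded: expected *permanent*); `slipping`
#' inserts discrete 2*pi slips (short linear ramps) into a locked difference
#' — the generator verifies by direct phasor averaging that the constructed
#' series still has coherence > 0.9 and retries with fewer slips otherwise
#' (expected *intermittent*); `drifting` applies a constant detuning spanning
#' at least 10 full cycles (coherence < 0.1: expected *none*).
#'
#' @param spec a [fixture_spec()] with a pair kind.
#' @return A tibble with columns `time`, `a`, `b`; the ground-truth label in
#'   `attr(, "expected")` and the spec in `attr(, "spec")`.
#' @export
make_pair_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!spec$kind %in% c("locked", "drifting", "slipping")) {
    stop("kind is not a pair kind", call. = FALSE)
  }
  set.seed(spec$seed)
  times <- seq(0, spec$duration, by = spec$sample_interval)
  nt <- length(times)
  omega <- fixture_par(spec, "omega", 2 * pi / 100)
  base <- omega * times
  offset <- fixture_par(spec, "offset", 1)
  jitter <- fixture_par(spec, "jitter", 0.05)

  if (spec$kind == "locked") {
    delta <- offset + runif(nt, -jitter, jitter)
    expected <- "permanent"
  } else if (spec$kind == "drifting") {
    detuning <- fixture_par(spec, "detuning", 0.05)
    if (abs(detuning) * spec$duration < 10 * 2 * pi) {
      stop("drifting fixture must span at least 10 full cycles",
           call. = FALSE)
    }
    delta <- detuning * times
    expected <- "none"
  } else {
    n_slips <- fixture_par(spec, "n_slips", 3)
    slip_duration <- fixture_par(spec, "slip_duration", 40)
    for (k in rev(seq_len(n_slips))) {
      jit <- runif(nt, -jitter, jitter)
      starts <- sort(runif(k, 0.1 * spec$duration, 0.85 * spec$duration))
      ramp <- rep(0, nt)
      for (s0 in starts) {
        ramp <- ramp + 2 * pi *
          pmin(1, pmax(0, (times - s0) / slip_duration))
      }
      delta <- offset + jit + ramp
      # verify the construction by brute-force phasor averaging
      coh <- abs(mean(complex(argument = delta)))
      if (coh > 0.9) break
      if (k == 1L) {
        stop("could not build a slipping fixture with coherence > 0.9",
             call. = FALSE)
      }
    }
    expected <- "intermittent"
  }

  out <- tibble::tibble(time = times, a = base + delta, b = base)
  attr(out, "expected") <- expected
  attr(out, "spec") <- spec
  out
}

#' Generate a labelled network fixture
#'
#' Builds a phase matrix whose order-parameter series realises the requested
#' network label. `ordered_network` draws a fixed phase scatter of circular
#' s.d. `spread` (constant `r ~ exp(-spread^2/2)`: expected *permanent*);
#' `disordered_network` redraws uniform phases at every sample
#' (`r_mean ~ sqrt(pi)/(2*sqrt(n))`: expected *disordered*);
#' `intermittent_network` alternates the scatter between `spread_low` and
#' `spread_high` in blocks (order parameter jumping between high and low
#' levels: expected *intermittent*). Spread parameters are checked against
#' the wrapped-normal closed form `r = exp(-sigma^2/2)` at generation time
#' and inconsistent requests error.
#'
#' @param spec a [fixture_spec()] with a network kind.
#' @return A list of class `network_fixture` with fields `times`, `phases`
#'   (matrix, rows = samples), `expected` and `spec`.
#' @export
make_network_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!spec$kind %in% c("ordered_network", "disordered_network",
                        "intermittent_network")) {
    stop("kind is not a network kind", call. = FALSE)
  }
  set.seed(spec$seed)
  times <- seq(0, spec$duration, by = spec$sample_interval)
  nt <- length(times)
  n <- fixture_par(spec, "n_osc", 100)
  omega <- fixture_par(spec, "omega", 2 * pi / 100)
  base <- omega * times

  if (spec$kind == "ordered_network") {
    spread <- fixture_par(spec, "spread", 0.3)
    if (exp(-spread^2 / 2) <= 0.55) {
      stop("spread too large for an ordered_network label ",
           "(closed-form r <= 0.55)", call. = FALSE)
    }
    scatter <- rnorm(n, 0, spread)
    phases <- outer(base, rep(1, n)) + matrix(scatter, nt, n, byrow = TRUE)
    expected <- "permanent"
  } else if (spec$kind == "disordered_network") {
    if (sqrt(pi) / (2 * sqrt(n)) >= 0.4) {
      stop("too few oscillators for a disordered_network label", call. = FALSE)
    }
    phases <- matrix(runif(nt * n, 0, 2 * pi), nt, n)
    expected <- "disordered"
  } else {
    lo <- fixture_par(spec, "spread_low", 0.3)
    hi <- fixture_par(spec, "spread_high", 1.5)
    period <- fixture_par(spec, "alternation", 250)
    r_lo <- exp(-hi^2 / 2)
    r_hi <- exp(-lo^2 / 2)
    if ((r_lo + r_hi) / 2 <= 0.55 || (r_hi - r_lo) <= 0.3) {
      stop("spread levels inconsistent with an intermittent_network label",
           call. = FALSE)
    }
    block <- floor(times / period)
    phases <- matrix(0, nt, n)
    for (bk in unique(block)) {
      sdv <- if (bk %% 2 == 0) lo else hi
      scatter <- rnorm(n, 0, sdv)
      rows <- which(block == bk)
      phases[rows, ] <- outer(base[rows], rep(1, n)) +
        matrix(scatter, length(rows), n, byrow = TRUE)
    }
    expected <- "intermittent"
  }

  structure(list(times = times, phases = phases, expected = expected,
                 spec = spec),
            class = "network_fixture")
}

#' @export
print.network_fixture <- function(x, ...) {
  cat("<network_fixture>", x$spec$kind, "expected:", x$expected, "-",
      nrow(x$phases), "samples x", ncol(x$phases), "oscillators\n")
  invisible(x)
}

#' Persist a fixture
#'
#' Writes the series as CSV plus a JSON sidecar holding the expected label
#' and the generating spec.
#'
#' @param fixture a [make_pair_fixture()] or [make_network_fixture()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (inherits(fixture, "network_fixture")) {
    df <- data.frame(time = fixture$times, fixture$phases)
    names(df) <- c("time", paste0("osc", seq_len(ncol(fixture$phases))))
    spec <- fixture$spec
    expected <- fixture$expected
  } else {
    df <- as.data.frame(fixture)
    spec <- attr(fixture, "spec")
    expected <- attr(fixture, "expected")
  }
  write.csv(df, file.path(dir, "series.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(expected = expected,
         spec = c(spec[c("kind", "duration", "sample_interval", "seed")],
                  spec$pars)),
    file.path(dir, "fixture.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
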