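#' Grid specification for the inter-network coupling sweep
#'
#' Defines the set of `F_GO` (and `F_MO`) values explored by [run_sweep()].
#' The defaults reproduce the reference 50 x 50 = 2,500-cell grid over
#' `[0, 0.3]` at steps of 0.006: the grid is anchored at zero (`0.006 * k`,
#' `k = 0..49`, so the last value is 0.294), because the zero-coupling
#' corners carry the interpretation of the map; `include_zero = FALSE`
#' selects the alternative reading `0.006 * k`, `k = 1..50`.
#'
#' @param f_min,f_max coupling range, rad/s.
#' @param step grid step, rad/s.
#' @param include_zero anchor the grid at `f_min` (default) or start one step
#'   above it.
#' @param allow_any_size permit grids of other than 50 values per axis.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(f_min = 0, f_max = 0.3, step = 0.006,
                      include_zero = TRUE, allow_any_size = FALSE) {
  stopifnot(step > 0, f_max > f_min)
  n <- as.integer(round((f_max - f_min) / step))
  if (n != 50L && !allow_any_size) {
    stop("grid is ", n, " values per axis, not 50; ",
         "set allow_any_size = TRUE to override", call. = FALSE)
  }
  structure(list(f_min = f_min, f_max = f_max, step = step,
                 include_zero = include_zero, n = n),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  v <- grid_values(x)
  cat("<grid_spec>", x$n, "values per axis:", format(v[1]), "...",
      format(v[length(v)]), "step", format(x$step), "\n")
  invisible(x)
}

#' Coupling values of a sweep grid
#'
#' @param spec a [grid_spec()].
#' @return Ordered numeric vector of coupling values (one axis).
#' @examples
#' head(grid_values(grid_spec()))   # 0, 0.006, 0.012, ...
#' @export
grid_values <- function(spec = grid_spec()) {
  stopifnot(inherits(spec, "grid_spec"))
  k <- if (spec$include_zero) 0:(spec$n - 1L) else 1:spec$n
  spec$f_min + spec$step * k
}

#' Presets for the regime-map sweep
#'
#' `"full"` is the reference protocol: the 50 x 50 grid at `N = M = 100`,
#' 10,000 s runs with 5,000 s transient (long-running; hours of CPU).
#' `"desk"` is the scaled-down protocol used for routine validation:
#' `N = M = 20`, 3,000 s runs with 1,500 s transient on a 10 x 10 grid
#' (steps of 0.03 over `[0, 0.27]`).
#'
#' @param name `"desk"` or `"full"`.
#' @param seed base seed.
#' @return A list with elements `grid` ([grid_spec()]), `config`
#'   ([model_config()]) and `spec` ([simulation_spec()]).
#' @export
sweep_preset <- function(name = c("desk", "full"), seed = 1L) {
  name <- match.arg(name)
  if (name == "full") {
    list(grid = grid_spec(),
         config = model_config(seed = seed),
         spec = simulation_spec())
  } else {
    list(grid = grid_spec(step = 0.03, allow_any_size = TRUE),
         config = model_config(N = 20, M = 20, seed = seed),
         spec = simulation_spec(t_total = 3000, t_transient = 1500))
  }
}

#' Sweep the inter-network coupling plane and map regimes
#'
#' Runs the model at every `(F_GO, F_MO)` combination of the grid: each cell
#' integrates the full model with its own derived seed (`config$seed + cell
#' index`, so results are independent of evaluation order and worker count),
#' discards the transient, and classifies the run into the six-mode regime.
#' Individual cell failures are recorded in the `status` column and the sweep
#' continues.
#'
#' @param grid a [grid_spec()].
#' @param config base [model_config()]; its `F_GO`, `F_MO` are overridden per
#'   cell.
#' @param spec a [simulation_spec()].
#' @param workers number of parallel workers (forked via the parallel
#'   package; results are identical for any worker count).
#' @param progress print a progress line per completed row of the grid.
#' @return A `regime_map`: a tibble with one row per cell (`F_GO`, `F_MO`,
#'   the six mode labels, `color`, `seed`, `status`) carrying the grid,
#'   config and spec as attributes.
#' @export
run_sweep <- function(grid = grid_spec(), config = model_config(),
                      spec = simulation_spec(), workers = 1L,
                      progress = FALSE) {
  stopifnot(inherits(grid, "grid_spec"), inherits(config, "model_config"),
            inherits(spec, "simulation_spec"))
  vals <- grid_values(grid)
  cells <- tidyr::expand_grid(F_GO = vals, F_MO = vals)
  cells$cell <- seq_len(nrow(cells))
  cells$seed <- config$seed + cells$cell

  run_cell <- function(k) {
    cfg <- config
    cfg$F_GO <- cells$F_GO[k]
    cfg$F_MO <- cells$F_MO[k]
    cfg$seed <- cells$seed[k]
    res <- tryCatch({
      series <- integrate_model(cfg, spec)
      series <- discard_transient(series, spec$t_transient)
      lab <- suppressWarnings(classify_regime(series, warn = FALSE))
      c(as.list(tibble::as_tibble(lab)[1, ]), list(status = "ok"))
    }, error = function(e) {
      list(go_g = NA_character_, go_net = NA_character_,
           go_mo = NA_character_, mo_go = NA_character_,
           mo_net = NA_character_, mo_o = NA_character_,
           color = NA_character_, status = paste("error:", conditionMessage(e)))
    })
    if (progress && k %% length(vals) == 0) {
      message("sweep: ", k, "/", nrow(cells), " cells")
    }
    res
  }

  if (workers > 1L && requireNamespace("parallel", quietly = TRUE) &&
      .Platform$OS.type == "unix") {
    verdicts <- parallel::mclapply(seq_len(nrow(cells)), run_cell,
                                   mc.cores = workers)
  } else {
    verdicts <- lapply(seq_len(nrow(cells)), run_cell)
  }

  out <- dplyr::bind_cols(
    cells[c("F_GO", "F_MO", "cell", "seed")],
    dplyr::bind_rows(lapply(verdicts, tibble::as_tibble))
  )
  attr(out, "grid") <- grid
  attr(out, "config") <- config
  attr(out, "spec") <- spec
  class(out) <- c("regime_map", class(out))
  out
}

#' @rdname run_sweep
#' @param x a `regime_map`.
#' @param ... unused.
#' @export
glance.regime_map <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    n_ok = sum(x$status == "ok"),
    n_colors = dplyr::n_distinct(x$color[x$status == "ok"]),
    n_unlisted = sum(x$color == "unlisted", na.rm = TRUE)
  )
}

#' @rdname run_sweep
#' @export
tidy.regime_map <- function(x, ...) tibble::as_tibble(x)

#' Persist a regime map
#'
#' Writes one CSV row per cell plus a JSON manifest (grid, base config,
#' simulation spec).
#'
#' @param map a [run_sweep()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_regime_map <- function(map, dir) {
  stopifnot(inherits(map, "regime_map"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(tibble::as_tibble(map), file.path(dir, "regime_map.csv"),
            row.names = FALSE)
  write_config(attr(map, "config"), file.path(dir, "config.json"))
  manifest <- list(grid = unclass(attr(map, "grid")),
                   spec = unclass(attr(map, "spec")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a regime map written by [write_regime_map()]
#'
#' @param dir directory holding `regime_map.csv`, `config.json`,
#'   `manifest.json`.
#' @return A `regime_map` tibble.
#' @export
read_regime_map <- function(dir) {
  df <- tibble::as_tibble(read.csv(file.path(dir, "regime_map.csv"),
                                   stringsAsFactors = FALSE))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  g <- manifest$grid
  attr(df, "grid") <- grid_spec(g$f_min, g$f_max, g$step, g$include_zero,
                                allow_any_size = TRUE)
  attr(df, "config") <- read_config(file.path(dir, "config.json"))
  attr(df, "spec") <- do.call(simulation_spec, as.list(manifest$spec))
  class(df) <- c("regime_map", class(df))
  df
}
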