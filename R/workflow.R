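# Workflow drivers tying the stages together: parameter sweeps with ensemble
# simulation + linear-stability overlay, phase diagrams, tidy CSV output and
# a JSON run manifest sufficient to re-run bit-identically.

#' Write a ring state as tidy CSV
#'
#' Columns: `compartment_type` (`cyto`/`apo`), `index`, `concentration_uM`,
#' `time`.
#'
#' @param state a [ring_state()].
#' @param path output path.
#' @param time time stamp to record (default `NA`).
#' @return `path`, invisibly.
#' @export
write_state_csv <- function(state, path, time = NA_real_) {
  stopifnot(inherits(state, "ring_state"))
  n <- length(state$A)
  df <- data.frame(
    compartment_type = rep(c("cyto", "apo"), each = n),
    index = rep(seq_len(n), 2),
    concentration_uM = c(state$A, state$a),
    time = time
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a ring state from tidy CSV
#'
#' @param path CSV written by [write_state_csv()].
#' @return a [ring_state()].
#' @export
read_state_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compartment_type", "index", "concentration_uM")
  if (!all(need %in% names(df)))
    stop("CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  cy <- df[df$compartment_type == "cyto", ]
  ap <- df[df$compartment_type == "apo", ]
  ring_state(cy$concentration_uM[order(cy$index)],
             ap$concentration_uM[order(ap$index)])
}

#' Ensemble sweep along one transport parameter
#'
#' For each value of the swept parameter (`I`, `E` or `D`), runs a replicate
#' ensemble ([run_ensemble()]) and the dispersion relation ([dispersion()]),
#' and collects per-replicate pattern statistics in long format together with
#' the theoretical wavenumber curve. Optionally writes `sweep_long.csv`,
#' `sweep_theory.csv` and `manifest.json` under `out_dir`; the CSVs are
#' byte-identical across re-runs of the same configuration.
#'
#' @param config a [simulation_config()]; the swept field of its `params` is
#'   overridden per grid point.
#' @param axis one of `"I"`, `"E"`, `"D"`.
#' @param values numeric grid (nonempty).
#' @param out_dir optional output directory (created if needed).
#' @return An object of class `sweep_result`: list with `long` (data.frame:
#'   `axis`, `axis_value`, `replicate`, `compartment`, `statistic`, `value`),
#'   `theory` (data.frame: `axis_value`, `max_growth`, `q_star`,
#'   `kappa_theory`, `is_patterning`), `failures`, `config`, `axis`,
#'   `values`, and `outputs` (paths written, if any).
#' @export
run_sweep <- function(config, axis = c("I", "E", "D"), values,
                      out_dir = NULL) {
  axis <- match.arg(axis)
  stopifnot(inherits(config, "simulation_config"), length(values) > 0)
  stats_cols <- c("n_maxima", "n_incipient_removed", "kappa_sim",
                  "amplitude", "avg_max", "avg_min", "mean_level")
  long <- list(); theory <- list(); failures <- list()
  for (v in values) {
    p <- unclass(config$params)
    p[[axis]] <- v
    p <- validate_transport_params(p)
    cfg <- config
    cfg$params <- p
    rep_lsa <- dispersion(p, config$n_cells)
    ens <- run_ensemble(cfg)
    if (length(ens$failures))
      failures[[as.character(v)]] <- ens$failures
    sm <- ens$summaries
    if (!is.null(sm)) {
      lf <- stats::reshape(
        sm[, c("replicate", "compartment", stats_cols)],
        direction = "long", varying = stats_cols, v.names = "value",
        times = stats_cols, timevar = "statistic",
        idvar = c("replicate", "compartment"))
      rownames(lf) <- NULL
      lf <- data.frame(axis = axis, axis_value = v, lf)
      long[[length(long) + 1L]] <- lf
    }
    theory[[length(theory) + 1L]] <- data.frame(
      axis_value = v, max_growth = rep_lsa$max_growth,
      q_star = rep_lsa$fastest_mode, kappa_theory = rep_lsa$kappa_theory,
      is_patterning = rep_lsa$is_patterning)
  }
  out <- structure(list(
    long = do.call(rbind, long), theory = do.call(rbind, theory),
    failures = failures, config = config, axis = axis, values = values,
    outputs = character(0)), class = "sweep_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f1 <- file.path(out_dir, "sweep_long.csv")
    f2 <- file.path(out_dir, "sweep_theory.csv")
    utils::write.csv(out$long, f1, row.names = FALSE, quote = FALSE)
    utils::write.csv(out$theory, f2, row.names = FALSE, quote = FALSE)
    out$outputs <- c(f1, f2)
    mf <- file.path(out_dir, "manifest.json")
    write_manifest(config, list(axis = axis, values = values),
                   out$outputs, mf)
    out$outputs <- c(out$outputs, mf)
  }
  out
}

#' Phase diagram driver
#'
#' Thin wrapper over [phase_diagram()] that optionally writes the grid as
#' `phase.csv` plus a manifest under `out_dir`.
#'
#' @inheritParams phase_diagram
#' @param out_dir optional output directory.
#' @return the [phase_diagram()] data.frame, with an `outputs` attribute when
#'   files were written.
#' @export
run_phase <- function(params, n_cells = 60, axis_x = "I", x_values,
                      axis_y = "D", y_values, out_dir = NULL) {
  grid <- phase_diagram(params, n_cells, axis_x, x_values, axis_y, y_values)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f <- file.path(out_dir, "phase.csv")
    utils::write.csv(grid, f, row.names = FALSE, quote = FALSE)
    mf <- file.path(out_dir, "manifest.json")
    write_manifest(simulation_config(params, n_cells = n_cells),
                   list(axis_x = axis_x, x_values = x_values,
                        axis_y = axis_y, y_values = y_values),
                   f, mf)
    attr(grid, "outputs") <- c(f, mf)
  }
  grid
}

# JSON manifest: config snapshot, grid, seeds, package version, timestamp,
# output inventory. Everything except the timestamp is deterministic.
write_manifest <- function(config, grid, outputs, path) {
  manifest <- list(
    package = "auxinring",
    version = as.character(utils::packageVersion("auxinring")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = c(unclass(config$params),
               config[setdiff(names(config), "params")]),
    grid = grid,
    seeds = config$base_seed + seq_len(config$n_replicates),
    outputs = basename(outputs)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
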