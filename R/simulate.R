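#' Noisy homogeneous initial condition
#'
#' Perturbs the homogeneous steady state multiplicatively:
#' `A_i = A* (1 + amp u_i)`, `a_j = a* (1 + amp v_j)` with `u, v` i.i.d.
#' uniform on (-1, 1) drawn from `seed`. Entries are clipped at 0 (only
#' possible when `amp >= 1`). `noise_amplitude = 0` returns the exact fixed
#' point; the same seed always returns the same state.
#'
#' @param params a [transport_params()].
#' @param n_cells ring size.
#' @param noise_amplitude relative perturbation amplitude (default 0.01).
#' @param seed integer RNG seed.
#' @return a [ring_state()].
#' @export
initial_state <- function(params, n_cells, noise_amplitude = 0.01, seed = 1L) {
  ss <- homogeneous_steady_state(params)
  if (noise_amplitude == 0)
    return(ring_state(rep(ss$A_star, n_cells), rep(ss$a_star, n_cells)))
  with_seed(seed, {
    u <- stats::runif(n_cells, -1, 1)
    v <- stats::runif(n_cells, -1, 1)
    ring_state(pmax(ss$A_star * (1 + noise_amplitude * u), 0),
               pmax(ss$a_star * (1 + noise_amplitude * v), 0))
  })
}

# evaluate code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  force(code)
}

#' Integrate the ring dynamics with fixed-step RK4
#'
#' Classical four-stage Runge-Kutta on the full coupled cell/apoplast system,
#' with fixed step `dt` (no adaptivity, mirroring the reference simulation
#' protocol). Runs in compiled code; the right-hand side is identical to
#' [rhs_ring()]. Aborts with the offending time if the state becomes
#' non-finite.
#'
#' @param state initial [ring_state()].
#' @param params a [transport_params()].
#' @param dt step size (nondimensional time), default `1e-4`.
#' @param t_end horizon, default 17.5.
#' @param snapshot_times optional times at which to record the state; each is
#'   snapped to the nearest step of the `dt` grid (so it is honoured within
#'   `dt/2`) and must not exceed `t_end`. The final state is always returned.
#' @return An object of class `ring_trajectory`: list with `final` (a
#'   [ring_state()]), `t_end` (realized final time), `snapshot_times`,
#'   `snapshots` (list with matrices `A`, `a`, one row per snapshot), `dt`,
#'   `params`.
#' @export
integrate_rk4 <- function(state, params, dt = 1e-4, t_end = 17.5,
                          snapshot_times = NULL) {
  stopifnot(inherits(state, "ring_state"), inherits(params, "transport_params"))
  n_steps <- round(t_end / dt)
  if (abs(n_steps * dt - t_end) > dt / 2 + 1e-12)
    n_steps <- floor(t_end / dt)
  snap_steps <- integer(0)
  if (!is.null(snapshot_times)) {
    snap_steps <- as.integer(round(sort(snapshot_times) / dt))
    if (any(snap_steps > n_steps))
      stop("snapshot time beyond t_end", call. = FALSE)
  }
  res <- .rk4_ring(state$A, state$a, unclass(params), dt, n_steps, snap_steps)
  structure(list(
    final = ring_state(pmax(res$A, 0), pmax(res$a, 0)),
    t_end = n_steps * dt, dt = dt, params = params,
    snapshot_times = if (length(snap_steps)) snap_steps * dt else numeric(0),
    snapshots = list(A = res$snapA, a = res$snapa)
  ), class = "ring_trajectory")
}

#' Run a replicate ensemble
#'
#' Integrates `n_replicates` trajectories from independently seeded noisy
#' initial conditions (replicate `r` uses seed `base_seed + r`) and
#' summarizes each final state with [summarize_pattern()]. Replicates that
#' abort are recorded, not dropped.
#'
#' @param config a [simulation_config()].
#' @return An object of class `ensemble_result`: list with `summaries`
#'   (data.frame: one row per replicate x compartment with the pattern
#'   statistics), `final_states` (list of [ring_state()]), `seeds`,
#'   `failures` (named list of error messages, empty when all ran), and
#'   `config`.
#' @export
run_ensemble <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  seeds <- config$base_seed + seq_len(config$n_replicates)
  finals <- vector("list", config$n_replicates)
  failures <- list()
  rows <- list()
  for (r in seq_len(config$n_replicates)) {
    res <- tryCatch({
      st <- initial_state(config$params, config$n_cells,
                          config$noise_amplitude, seeds[r])
      integrate_rk4(st, config$params, config$dt, config$t_end,
                    config$snapshot_times)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[as.character(r)]] <- conditionMessage(res)
      next
    }
    finals[[r]] <- res$final
    sm <- summarize_pattern(res$final)
    sm$replicate <- r
    sm$seed <- seeds[r]
    rows[[r]] <- sm
  }
  summaries <- do.call(rbind, rows)
  if (!is.null(summaries)) rownames(summaries) <- NULL
  structure(list(summaries = summaries, final_states = finals,
                 seeds = seeds, failures = failures, config = config),
            class = "ensemble_result")
}
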