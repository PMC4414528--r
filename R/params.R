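#' Transport parameters for the ring model
#'
#' Bundles every rate constant and saturation threshold of the polar-transport
#' dynamics. Defaults are the reference operating point used throughout the
#' analyses: active efflux `E = 105` uM/s, active influx `I = 100` uM/s,
#' apoplastic diffusion `D = 2` /s, passive influx `D_ca = 15` /s and carrier
#' half-saturation `theta_I = theta_P = 10` uM. Production and degradation are
#' chosen so the homogeneous cytosolic level `A* = sigma_c/nu_c = 10` uM sits
#' at the carrier half-saturation point, keeping auxin-induced carrier
#' synthesis responsive.
#'
#' Printed transport intensities `I` and `E` carry units of uM/s while the
#' fluxes themselves are linear in the transported concentration; the two are
#' reconciled by fixed reference concentrations `a_ref` and `A_ref` (1 uM)
#' dividing the transported pool, so printed parameter values are used as-is.
#'
#' @param I active influx intensity (uM/s); proportional to the maximal
#'   amount of influx carriers a cell can hold.
#' @param E active efflux intensity (uM/s).
#' @param D effective apoplastic diffusion rate (/s) between adjacent wall
#'   compartments.
#' @param D_ca passive (chemiosmotic) influx rate (/s); strictly inward.
#' @param sigma_c auxin production rate inside cells (uM per unit time).
#' @param nu_c auxin degradation rate inside cells (per unit time).
#' @param theta_I,theta_P half-saturation auxin concentrations (uM) for the
#'   auxin-induced synthesis of influx and efflux carriers. Setting both to 0
#'   gives the constant-carrier variant (carrier totals fixed at 1/2 and 1).
#' @param rho cell-to-apoplast volume ratio `V_cell / V_ap` (dimensionless).
#' @param w membrane area-to-volume factor folded into an effective
#'   dimensionless rate multiplier.
#' @param a_ref,A_ref reference concentrations (uM) making the printed units
#'   of `I` and `E` consistent with linear fluxes.
#' @param polarity_exponent exponent of the efflux-polarization weighting of
#'   the two neighbour cytosolic concentrations.
#' @param time_scale factor converting dimensional time to the reported
#'   nondimensional time.
#' @return An object of class `transport_params` (a validated named list).
#' @seealso [homogeneous_steady_state()], [dispersion()], [load_config()]
#' @export
#' @examples
#' p <- transport_params()
#' p$E
#' transport_params(theta_I = 0, theta_P = 0)  # constant-carrier variant
transport_params <- function(I = 100, E = 105, D = 2, D_ca = 15,
                             sigma_c = 5, nu_c = 0.5,
                             theta_I = 10, theta_P = 10,
                             rho = 5, w = 1,
                             a_ref = 1, A_ref = 1,
                             polarity_exponent = 1, time_scale = 1) {
  p <- list(I = I, E = E, D = D, D_ca = D_ca,
            sigma_c = sigma_c, nu_c = nu_c,
            theta_I = theta_I, theta_P = theta_P,
            rho = rho, w = w, a_ref = a_ref, A_ref = A_ref,
            polarity_exponent = polarity_exponent, time_scale = time_scale)
  validate_transport_params(p)
}

validate_transport_params <- function(p) {
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("transport_params: field '", nm, "' must be a single finite number",
           call. = FALSE)
  }
  nonneg <- c("I", "E", "D", "D_ca", "sigma_c", "nu_c", "theta_I", "theta_P",
              "polarity_exponent", "time_scale", "w")
  for (nm in nonneg)
    if (p[[nm]] < 0) stop("transport_params: '", nm, "' must be >= 0",
                          call. = FALSE)
  for (nm in c("rho", "a_ref", "A_ref"))
    if (p[[nm]] <= 0) stop("transport_params: '", nm, "' must be > 0",
                           call. = FALSE)
  structure(p, class = "transport_params")
}

#' @export
print.transport_params <- function(x, ...) {
  cat("<transport_params>\n")
  cat(sprintf("  I = %g uM/s, E = %g uM/s, D = %g /s, D_ca = %g /s\n",
              x$I, x$E, x$D, x$D_ca))
  cat(sprintf("  sigma_c = %g, nu_c = %g (A* = %g uM), theta_I = %g, theta_P = %g uM\n",
              x$sigma_c, x$nu_c,
              if (x$nu_c > 0) x$sigma_c / x$nu_c else NA_real_,
              x$theta_I, x$theta_P))
  cat(sprintf("  rho = %g, w = %g, refs = (%g, %g) uM, polarity n = %g, time_scale = %g\n",
              x$rho, x$w, x$a_ref, x$A_ref, x$polarity_exponent, x$time_scale))
  invisible(x)
}

#' Simulation configuration
#'
#' Everything needed to reproduce one ensemble run: transport parameters, ring
#' size, integrator step, horizon, initial noise, replicate count and seeding
#' policy. Defaults mirror the reference simulation protocol: 60 cells,
#' fixed step `dt = 1e-4` in nondimensional time, horizon `t = 17.5`,
#' 30 replicates started from the homogeneous state with 1% multiplicative
#' uniform noise, replicate r seeded with `base_seed + r`.
#'
#' @param params a [transport_params()] object.
#' @param n_cells number of cells (= number of apoplastic compartments).
#' @param dt integrator step (nondimensional time).
#' @param t_end integration horizon (nondimensional time).
#' @param noise_amplitude relative amplitude of the initial multiplicative
#'   uniform perturbation around the homogeneous state.
#' @param n_replicates ensemble size.
#' @param base_seed integer; replicate r uses seed `base_seed + r`.
#' @param snapshot_times optional numeric vector of times at which the full
#'   ring state is recorded (snapped to the nearest `dt` step).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(params = transport_params(), n_cells = 60,
                              dt = 1e-4, t_end = 17.5,
                              noise_amplitude = 0.01, n_replicates = 30,
                              base_seed = 1L, snapshot_times = NULL) {
  stopifnot(inherits(params, "transport_params"))
  if (!is.numeric(n_cells) || n_cells < 3 || n_cells != round(n_cells))
    stop("n_cells must be an integer >= 3", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (!is.numeric(t_end) || t_end < dt)
    stop("t_end must be >= dt", call. = FALSE)
  if (noise_amplitude < 0) stop("noise_amplitude must be >= 0", call. = FALSE)
  if (n_replicates < 1 || n_replicates != round(n_replicates))
    stop("n_replicates must be a positive integer", call. = FALSE)
  if (!is.null(snapshot_times) &&
      any(snapshot_times < 0 | snapshot_times > t_end + dt / 2))
    stop("snapshot_times must lie in [0, t_end]", call. = FALSE)
  structure(list(params = params, n_cells = as.integer(n_cells), dt = dt,
                 t_end = t_end, noise_amplitude = noise_amplitude,
                 n_replicates = as.integer(n_replicates),
                 base_seed = as.integer(base_seed),
                 snapshot_times = snapshot_times),
            class = "simulation_config")
}

# All keys load_config() accepts, with their home in the config tree.
config_param_keys <- function() names(formals(transport_params))
config_sim_keys <- function() {
  setdiff(names(formals(simulation_config)), "params")
}

#' Read a simulation configuration from a YAML/JSON file
#'
#' The file is a flat key-value mapping. Keys naming transport parameters
#' (`I`, `E`, `D`, `D_ca`, `sigma_c`, `nu_c`, `theta_I`, `theta_P`, `rho`,
#' `w`, `a_ref`, `A_ref`, `polarity_exponent`, `time_scale`) and simulation
#' fields (`n_cells`, `dt`, `t_end`, `noise_amplitude`, `n_replicates`,
#' `base_seed`, `snapshot_times`) may appear in any order; anything missing is
#' filled from the defaults (the reference operating point), every resolved
#' value is validated, and unknown keys are rejected by name. An empty file
#' yields the full default configuration.
#'
#' @param path path to a YAML (or JSON, which YAML subsumes) file.
#' @return A [simulation_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a key-value mapping", call. = FALSE)
  pk <- config_param_keys()
  sk <- config_sim_keys()
  unknown <- setdiff(names(raw), c(pk, sk))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  params <- do.call(transport_params, raw[intersect(names(raw), pk)])
  do.call(simulation_config,
          c(list(params = params), raw[intersect(names(raw), sk)]))
}

#' Write a simulation configuration to a YAML file
#'
#' Inverse of [load_config()]: `load_config(save_config(cfg, f))` reproduces
#' `cfg` exactly.
#'
#' @param config a [simulation_config()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  flat <- c(unclass(config$params),
            config[setdiff(names(config), "params")])
  flat <- flat[!vapply(flat, is.null, logical(1))]
  yaml::write_yaml(flat, path)
  invisible(path)
}
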