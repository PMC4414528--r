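#' Ring geometry and state
#'
#' The tissue is a periodic ring of `n_cells` cells with one apoplastic (cell
#' wall) compartment between each pair of adjacent cells, so there are exactly
#' `n_cells` apoplasts. Apoplast `i` sits between cell `i` and cell `i + 1`
#' (indices mod `n_cells`); the apoplasts adjacent to cell `i` are therefore
#' apoplasts `i - 1` (left) and `i` (right).
#'
#' @param n_cells integer >= 3.
#' @return An object of class `ring_geometry`.
#' @export
ring_geometry <- function(n_cells) {
  if (!is.numeric(n_cells) || length(n_cells) != 1L ||
      n_cells != round(n_cells) || n_cells < 3)
    stop("n_cells must be an integer >= 3", call. = FALSE)
  structure(list(n_cells = as.integer(n_cells)), class = "ring_geometry")
}

#' @describeIn ring_geometry Paired cytosolic/apoplastic concentration state.
#'   `A` is cytosolic auxin per cell, `a` apoplastic auxin per wall
#'   compartment (both uM, nonnegative, equal length >= 3).
#' @param A numeric vector of cytosolic auxin concentrations (uM).
#' @param a numeric vector of apoplastic auxin concentrations (uM).
#' @export
ring_state <- function(A, a) {
  if (length(A) != length(a))
    stop("A and a must have the same length", call. = FALSE)
  if (length(A) < 3) stop("ring must have at least 3 cells", call. = FALSE)
  if (!all(is.finite(A)) || !all(is.finite(a)))
    stop("non-finite concentration in state", call. = FALSE)
  if (any(A < 0) || any(a < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  structure(list(A = as.numeric(A), a = as.numeric(a)),
            class = "ring_state")
}

# circular shifts: left neighbour value of i is x[i-1], right is x[i+1]
shift_left <- function(x) c(x[length(x)], x[-length(x)])   # x[i-1]
shift_right <- function(x) c(x[-1], x[1])                  # x[i+1]

#' Carrier totals induced by cytosolic auxin
#'
#' Total per-cell influx- and efflux-carrier levels as saturating functions of
#' cytosolic auxin: `I_T(A) = (1/2) A / (theta_I + A)` and
#' `P_T(A) = A / (theta_P + A)` (influx carriers normalized to 1/2, efflux to
#' 1). With `theta_I = theta_P = 0` the carrier totals are constant at
#' (1/2, 1) for every cell, including at `A = 0`, which is the
#' constant-carrier (no auxin-induced synthesis) variant of the model.
#'
#' @param A numeric vector of cytosolic auxin concentrations (uM), >= 0.
#' @param params a [transport_params()] object (uses `theta_I`, `theta_P`).
#' @return list with components `i_tot` (in `[0, 1/2]`) and `p_tot`
#'   (in `[0, 1]`), one entry per cell.
#' @export
#' @examples
#' carrier_totals(10, transport_params())  # half-saturation: 0.25, 0.5
carrier_totals <- function(A, params) {
  if (any(A < 0)) stop("negative cytosolic auxin", call. = FALSE)
  i_tot <- if (params$theta_I == 0) rep(0.5, length(A))
           else 0.5 * A / (params$theta_I + A)
  p_tot <- if (params$theta_P == 0) rep(1, length(A))
           else A / (params$theta_P + A)
  # A = 0 with theta > 0: zero auxin induces no carriers
  i_tot[A == 0 & params$theta_I > 0] <- 0
  p_tot[A == 0 & params$theta_P > 0] <- 0
  list(i_tot = i_tot, p_tot = p_tot)
}

#' Polar distribution of efflux carriers
#'
#' Efflux carriers localize toward the neighbour with more cytosolic auxin,
#' at equilibrium. The fraction on the membrane of cell `i` facing apoplast
#' `i` (toward cell `i + 1`) is `A[i+1]^n / (A[i+1]^n + A[i-1]^n)` with `n`
#' the polarity exponent; the remainder faces apoplast `i - 1`. If both
#' neighbour weights vanish (or underflow) the split is 1/2-1/2, keeping the
#' dynamics continuous at the origin.
#'
#' @param A cytosolic auxin vector (uM), >= 0.
#' @param polarity_exponent exponent `n` of the weighting (default 1).
#' @return list with `phi_left` and `phi_right`, each summing to 1 per cell.
#' @export
efflux_polarization <- function(A, polarity_exponent = 1) {
  if (any(A < 0)) stop("negative cytosolic auxin", call. = FALSE)
  n <- polarity_exponent
  wr <- shift_right(A)^n
  wl <- shift_left(A)^n
  tot <- wr + wl
  phi_right <- ifelse(tot > 0, wr / tot, 0.5)
  phi_left <- 1 - phi_right
  list(phi_left = phi_left, phi_right = phi_right)
}

#' Membrane fluxes between each cell and its two adjacent apoplasts
#'
#' Net flux from cell `i` into apoplast `j` (positive outward):
#' `J(i -> j) = E p_tot(A_i) phi_ij (A_i / A_ref)
#'            - I i_tot(A_i) (a_j / a_ref) - D_ca a_j`.
#' Active efflux acts only outward; active influx and passive chemiosmotic
#' entry act only inward (protonated auxin is trapped once deprotonated in
#' the cytosol, so there is no passive efflux). All fluxes are linear in the
#' transported concentration.
#'
#' @param state a [ring_state()].
#' @param params a [transport_params()].
#' @return list with `J_left` (cell i -> apoplast i-1) and `J_right`
#'   (cell i -> apoplast i), one entry per cell.
#' @export
membrane_fluxes <- function(state, params) {
  stopifnot(inherits(state, "ring_state"))
  A <- state$A; a <- state$a
  ct <- carrier_totals(A, params)
  phi <- efflux_polarization(A, params$polarity_exponent)
  efflux <- params$E * ct$p_tot * (A / params$A_ref)
  a_left <- shift_left(a)    # apoplast i-1
  uptake <- params$I * ct$i_tot / params$a_ref + params$D_ca
  list(J_left = efflux * phi$phi_left - uptake * a_left,
       J_right = efflux * phi$phi_right - uptake * a)
}

#' Time derivatives of the ring dynamics
#'
#' Reference (pure R) right-hand side of the coupled cell/apoplast system:
#' \deqn{dA_i/dt = -w \sum_j J(i \to j) - \nu_c A_i + \sigma_c}
#' \deqn{da_j/dt = +w \rho \sum_i J(i \to j) + D (a_{j-1} - 2 a_j + a_{j+1})}
#' with periodic wrap, everything multiplied by `time_scale`. Production and
#' degradation act only inside cells. The compiled integrator implements the
#' identical expressions; this version is kept as the readable reference and
#' for Jacobian cross-checks.
#'
#' @param state a [ring_state()].
#' @param params a [transport_params()].
#' @return list with numeric vectors `dA` and `da`.
#' @export
rhs_ring <- function(state, params) {
  if (!all(is.finite(state$A)) || !all(is.finite(state$a)))
    stop("non-finite state passed to rhs_ring", call. = FALSE)
  J <- membrane_fluxes(state, params)
  a <- state$a
  dA <- -params$w * (J$J_left + J$J_right) -
    params$nu_c * state$A + params$sigma_c
  # apoplast j receives from cell j (its right membrane) and cell j+1 (left)
  influx_from_cells <- J$J_right + shift_right(J$J_left)
  da <- params$w * params$rho * influx_from_cells +
    params$D * (shift_left(a) - 2 * a + shift_right(a))
  list(dA = params$time_scale * dA, da = params$time_scale * da)
}

#' Homogeneous steady state
#'
#' At a spatially uniform fixed point apoplastic diffusion vanishes and
#' production must balance degradation, so `A* = sigma_c / nu_c`. Each
#' membrane then carries half the efflux carriers and the per-side flux
#' balance `E P_T(A*) (1/2) (A*/A_ref) = (I I_T(A*)/a_ref + D_ca) a*`
#' determines the apoplastic level. Requires `nu_c > 0`.
#'
#' @param params a [transport_params()].
#' @return list with scalars `A_star` and `a_star` (uM).
#' @export
#' @examples
#' homogeneous_steady_state(transport_params())
homogeneous_steady_state <- function(params) {
  if (params$nu_c <= 0)
    stop("nu_c must be > 0 for a finite homogeneous state", call. = FALSE)
  A_star <- params$sigma_c / params$nu_c
  ct <- carrier_totals(A_star, params)
  num <- params$E * ct$p_tot * (A_star / params$A_ref) / 2
  den <- params$I * ct$i_tot / params$a_ref + params$D_ca
  a_star <- if (num == 0) 0
            else if (den == 0) stop("no finite apoplastic steady state: ",
                                    "efflux with no uptake", call. = FALSE)
            else num / den
  list(A_star = A_star, a_star = a_star)
}
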