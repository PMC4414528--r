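# Linear stability analysis about the homogeneous steady state.
#
# The linearized system is block-circulant on the ring, so its 2N x 2N
# Jacobian diagonalizes into 2 x 2 Fourier blocks, one per integer mode q.
# The per-mode growth rate is the largest real part of the block eigenvalues;
# the fastest-growing mode among q >= 1 predicts the number of auxin maxima.

# derivative of P_T / I_T with respect to A
p_tot_deriv <- function(A, theta) {
  if (theta == 0) rep(0, length(A)) else theta / (theta + A)^2
}
i_tot_deriv <- function(A, theta) {
  if (theta == 0) rep(0, length(A)) else 0.5 * theta / (theta + A)^2
}

#' Analytic Jacobian of the ring dynamics
#'
#' Exact linearization of [rhs_ring()] at an arbitrary state (by default the
#' homogeneous steady state), including the derivatives of the equilibrium
#' efflux-carrier polarization with respect to the two neighbour cytosolic
#' concentrations. Variable order is `(A_1..A_N, a_1..a_N)`.
#'
#' @param params a [transport_params()].
#' @param n_cells ring size.
#' @param state optional [ring_state()] to linearize about; defaults to the
#'   homogeneous steady state.
#' @return a `2 n_cells x 2 n_cells` numeric matrix.
#' @export
auxin_jacobian <- function(params, n_cells, state = NULL) {
  N <- as.integer(n_cells)
  if (is.null(state)) {
    ss <- homogeneous_steady_state(params)
    state <- ring_state(rep(ss$A_star, N), rep(ss$a_star, N))
  }
  stopifnot(length(state$A) == N)
  A <- state$A; a <- state$a
  ts <- params$time_scale
  w <- params$w; rho <- params$rho; D <- params$D; nu <- params$nu_c
  Eref <- params$E / params$A_ref
  ct <- carrier_totals(A, params)
  P <- ct$p_tot; Ip <- ct$i_tot
  Pp <- p_tot_deriv(A, params$theta_P)
  Ipp <- i_tot_deriv(A, params$theta_I)
  eff <- Eref * (Pp * A + P)           # d(E P_T A / A_ref)/dA
  upt <- params$I * Ip / params$a_ref + params$D_ca
  uptd <- params$I * Ipp / params$a_ref
  n <- params$polarity_exponent

  ip1 <- c(2:N, 1); im1 <- c(N, 1:(N - 1)); ip2 <- ip1[ip1]
  # polarization phi_right(i) = x^n / (x^n + y^n), x = A[i+1], y = A[i-1]
  x <- A[ip1]; y <- A[im1]
  s <- x^n + y^n
  phiR <- ifelse(s > 0, x^n / s, 0.5)
  phiL <- 1 - phiR
  dphiR_dx <- ifelse(s > 0, n * x^(n - 1) * y^n / s^2, 0)
  dphiR_dy <- ifelse(s > 0, -n * y^(n - 1) * x^n / s^2, 0)
  dphiR_dx[!is.finite(dphiR_dx)] <- 0
  dphiR_dy[!is.finite(dphiR_dy)] <- 0

  J <- matrix(0, 2 * N, 2 * N)
  idxA <- 1:N; idxa <- N + 1:N
  # cytosolic rows: total efflux is independent of the polarization split
  a_left <- a[im1]
  diagA <- ts * (-w * (eff - uptd * (a_left + a)) - nu)
  J[cbind(idxA, idxA)] <- diagA
  J[cbind(idxA, idxa)] <- ts * w * upt
  J[cbind(idxA, N + im1)] <- ts * w * upt

  # apoplastic rows: apoplast j is fed by cell j (right membrane) and
  # cell j+1 (left membrane)
  efPA <- Eref * P * A                 # E P_T A / A_ref per cell
  # wrt A_j: J_R(j) direct + polarization of cell j+1 (A_j is its left nbr)
  J[cbind(idxa, idxA)] <- ts * w * rho *
    (eff * phiR - uptd * a - efPA[ip1] * dphiR_dy[ip1])
  # wrt A_{j+1}: polarization of cell j + direct term of J_L(j+1)
  J[cbind(idxa, ip1)] <- ts * w * rho *
    (efPA * dphiR_dx + eff[ip1] * phiL[ip1] - uptd[ip1] * a)
  # wrt A_{j-1}: polarization of cell j
  J[cbind(idxa, im1)] <- J[cbind(idxa, im1)] +
    ts * w * rho * (efPA * dphiR_dy)
  # wrt A_{j+2}: polarization of cell j+1
  J[cbind(idxa, ip2)] <- J[cbind(idxa, ip2)] -
    ts * w * rho * (efPA[ip1] * dphiR_dx[ip1])
  # apoplast-apoplast: uptake by both flanking cells plus diffusion
  J[cbind(idxa, idxa)] <- J[cbind(idxa, idxa)] +
    ts * (-w * rho * (upt + upt[ip1]) - 2 * D)
  J[cbind(idxa, N + ip1)] <- J[cbind(idxa, N + ip1)] + ts * D
  J[cbind(idxa, N + im1)] <- J[cbind(idxa, N + im1)] + ts * D
  J
}

# circulant coefficients of the linearization at the homogeneous state;
# used to build the 2x2 Fourier blocks without assembling the full matrix
dispersion_coefs <- function(params) {
  ss <- homogeneous_steady_state(params)
  A <- ss$A_star; a <- ss$a_star
  ct <- carrier_totals(A, params)
  Eref <- params$E / params$A_ref
  eff <- Eref * (p_tot_deriv(A, params$theta_P) * A + ct$p_tot)
  upt <- params$I * ct$i_tot / params$a_ref + params$D_ca
  uptd <- params$I * i_tot_deriv(A, params$theta_I) / params$a_ref
  # d phi_right / d A_neighbour at the uniform state is n / (4 A*)
  pol <- if (A > 0) Eref * ct$p_tot * A * params$polarity_exponent / (4 * A)
         else 0
  w <- params$w; rho <- params$rho
  list(
    A_star = A, a_star = a,
    cAA = -w * (eff - 2 * uptd * a) - params$nu_c,
    cAa = w * upt,                       # offsets 0 and -1
    caA0 = w * rho * (eff / 2 - uptd * a + pol),
    caA1 = w * rho * (eff / 2 - uptd * a + pol),
    caAm1 = -w * rho * pol,
    caA2 = -w * rho * pol,
    caa0 = -2 * w * rho * upt - 2 * params$D,
    D = params$D, ts = params$time_scale
  )
}

# 2x2 Fourier block for mode q on a ring of N cells
fourier_block <- function(co, q, N) {
  om <- exp(2i * pi * q / N)
  B <- matrix(c(
    co$cAA,
    co$caA0 + co$caA1 * om + co$caAm1 / om + co$caA2 * om^2,
    co$cAa * (1 + 1 / om),
    co$caa0 + co$D * (om + 1 / om)
  ), 2, 2)
  co$ts * B
}

#' Dispersion relation and pattern prediction
#'
#' Computes the per-mode growth rate (largest real part of the 2 x 2 Fourier
#' block eigenvalues) for wavenumbers `q = 0 .. floor(N/2)`, classifies the
#' parameter set as patterning (some `q >= 1` grows) or homogeneous, and
#' predicts the characteristic wavenumber `kappa = q*/N` from the
#' fastest-growing mode. Ties for the fastest mode break toward the smaller
#' `q` (the longer wavelength).
#'
#' @param params a [transport_params()].
#' @param n_cells ring size (default 60).
#' @return An object of class `stability_report`: list with `growth_rates`
#'   (named by mode), `modes`, `fastest_mode`, `max_growth`, `kappa_theory`,
#'   `is_patterning`, `n_cells`, `params`.
#' @export
#' @examples
#' rep <- dispersion(transport_params(), 60)
#' rep$is_patterning
#' rep$kappa_theory
dispersion <- function(params, n_cells = 60) {
  N <- as.integer(n_cells)
  co <- dispersion_coefs(params)
  modes <- 0:(N %/% 2)
  growth <- vapply(modes, function(q) {
    max(Re(eigen(fourier_block(co, q, N), only.values = TRUE)$values))
  }, numeric(1))
  gpos <- growth[-1]
  max_growth <- max(gpos)
  qstar <- modes[-1][which.max(gpos)]   # which.max takes the smallest q on ties
  structure(list(params = params, n_cells = N, modes = modes,
                 growth_rates = growth, fastest_mode = qstar,
                 max_growth = max_growth, kappa_theory = qstar / N,
                 is_patterning = max_growth > 0),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> N = %d: %s (max growth %.4g at q* = %d, kappa = %.4g)\n",
              x$n_cells, if (x$is_patterning) "patterning (P)" else "homogeneous (H)",
              x$max_growth, x$fastest_mode, x$kappa_theory))
  invisible(x)
}

#' Phase diagram over a parameter grid
#'
#' Runs [dispersion()] on every point of a rectangular grid in two transport
#' parameters (typically influx `I` against apoplastic diffusion `D`, or
#' influx `I` against efflux `E`) and returns the classification and
#' predicted wavenumber per point. The homogeneous/patterning boundary is the
#' `is_patterning` contour.
#'
#' @param params baseline [transport_params()]; grid axes override its fields.
#' @param n_cells ring size.
#' @param axis_x,axis_y names of the swept parameters (fields of
#'   `transport_params`).
#' @param x_values,y_values numeric grid values.
#' @return a data.frame with columns `<axis_x>`, `<axis_y>`, `max_growth`,
#'   `q_star`, `kappa`, `is_patterning`.
#' @export
phase_diagram <- function(params, n_cells = 60,
                          axis_x = "I", x_values,
                          axis_y = "D", y_values) {
  stopifnot(axis_x %in% config_param_keys(), axis_y %in% config_param_keys(),
            length(x_values) > 0, length(y_values) > 0)
  grid <- expand.grid(x = x_values, y = y_values, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(k) {
    p <- unclass(params)
    p[[axis_x]] <- grid$x[k]
    p[[axis_y]] <- grid$y[k]
    r <- dispersion(validate_transport_params(p), n_cells)
    data.frame(x = grid$x[k], y = grid$y[k], max_growth = r$max_growth,
               q_star = r$fastest_mode, kappa = r$kappa_theory,
               is_patterning = r$is_patterning)
  })
  out <- do.call(rbind, res)
  names(out)[1:2] <- c(axis_x, axis_y)
  out
}
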