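test_that("carrier totals follow the saturating synthesis curves", {
  p <- transport_params()  # theta_I = theta_P = 10
  ct <- carrier_totals(c(0, 10, 1e6), p)
  expect_equal(ct$i_tot, c(0, 0.25, 0.5), tolerance = 1e-5)
  expect_equal(ct$p_tot, c(0, 0.50, 1.0), tolerance = 1e-5)
  # constant-carrier variant: totals pinned at (1/2, 1) everywhere
  p0 <- transport_params(theta_I = 0, theta_P = 0)
  ct0 <- carrier_totals(c(0, 0.3, 50), p0)
  expect_identical(ct0$i_tot, rep(0.5, 3))
  expect_identical(ct0$p_tot, rep(1, 3))
  expect_error(carrier_totals(c(1, -1), p), "negative")
})

test_that("efflux polarization weights neighbours and splits ties evenly", {
  # uniform ring: symmetric split
  phi <- efflux_polarization(rep(3, 8))
  expect_equal(phi$phi_right, rep(0.5, 8))
  # cell 2 with neighbours A1 = 0 (left), A3 = 3 (right): all carriers right
  phi <- efflux_polarization(c(0, 5, 3))
  expect_equal(phi$phi_right[2], 1)
  expect_equal(phi$phi_left[2], 0)
  # both neighbours zero: tie rule
  phi <- efflux_polarization(c(0, 7, 0))
  expect_equal(phi$phi_right[2], 0.5)
  # fractions always sum to one
  set.seed(1)
  A <- runif(11, 0, 30)
  for (n in c(1, 2)) {
    phi <- efflux_polarization(A, n)
    expect_equal(phi$phi_left + phi$phi_right, rep(1, 11))
  }
})

test_that("membrane fluxes vanish without transport and are linear in the
           transported pool", {
  p0 <- transport_params(I = 0, E = 0, D_ca = 0)
  st <- ring_state(runif(6, 1, 10), runif(6, 1, 10))
  J <- membrane_fluxes(st, p0)
  expect_equal(J$J_left, rep(0, 6))
  expect_equal(J$J_right, rep(0, 6))
  # doubling apoplastic auxin doubles the inward (negative) components
  p <- transport_params(E = 0)
  st1 <- ring_state(rep(10, 6), rep(2, 6))
  st2 <- ring_state(rep(10, 6), rep(4, 6))
  expect_equal(2 * membrane_fluxes(st1, p)$J_right,
               membrane_fluxes(st2, p)$J_right)
})

test_that("net flux balances at the homogeneous fixed point", {
  set.seed(7)
  for (k in 1:10) {
    p <- random_params()
    ss <- homogeneous_steady_state(p)
    st <- ring_state(rep(ss$A_star, 9), rep(ss$a_star, 9))
    J <- membrane_fluxes(st, p)
    expect_lt(max(abs(J$J_left + J$J_right)), 1e-10 * max(1, ss$A_star))
  }
})

test_that("transport conserves total mass when production and degradation
           are off", {
  set.seed(3)
  p <- transport_params(sigma_c = 0, nu_c = 0)
  st <- ring_state(runif(20, 1, 20), runif(20, 0.1, 10))
  d <- rhs_ring(st, p)
  expect_lt(abs(sum(d$dA) + sum(d$da) / p$rho), 1e-10)
  # rho enters the cell/apoplast bookkeeping
  p2 <- transport_params(sigma_c = 0, nu_c = 0, rho = 3.7)
  d2 <- rhs_ring(st, p2)
  expect_lt(abs(sum(d2$dA) + sum(d2$da) / p2$rho), 1e-10)
})

test_that("dynamics commute with ring rotation and reflection", {
  set.seed(11)
  p <- transport_params()
  A <- runif(12, 1, 20); a <- runif(12, 0.5, 8)
  d <- rhs_ring(ring_state(A, a), p)
  for (k in c(1, 5)) {
    dr <- rhs_ring(ring_state(rotate_ring(A, k), rotate_ring(a, k)), p)
    expect_equal(dr$dA, rotate_ring(d$dA, k), tolerance = 1e-12)
    expect_equal(dr$da, rotate_ring(d$da, k), tolerance = 1e-12)
  }
  # mirror: cell i -> N+1-i maps apoplast i to apoplast N-i (wall between
  # mirrored neighbours), i.e. reversed a shifted by one
  mirrA <- rev(A)
  mirra <- rotate_ring(rev(a), 1)
  dm <- rhs_ring(ring_state(mirrA, mirra), p)
  expect_equal(dm$dA, rev(d$dA), tolerance = 1e-12)
  expect_equal(dm$da, rotate_ring(rev(d$da), 1), tolerance = 1e-12)
})

test_that("homogeneous steady state is an exact fixed point", {
  p <- transport_params()
  ss <- homogeneous_steady_state(p)
  expect_equal(ss$A_star, p$sigma_c / p$nu_c)
  st <- ring_state(rep(ss$A_star, 60), rep(ss$a_star, 60))
  expect_lt(max_abs_rhs(p, st), 1e-10)
  # no efflux: apoplast drains
  expect_equal(homogeneous_steady_state(transport_params(E = 0))$a_star, 0)
  # no source: all-zero state
  ss0 <- homogeneous_steady_state(transport_params(sigma_c = 0))
  expect_equal(c(ss0$A_star, ss0$a_star), c(0, 0))
  expect_error(homogeneous_steady_state(transport_params(nu_c = 0)), "nu_c")
})

test_that("homogeneous steady state matches a damped-Newton root find on the
           uniform dynamics", {
  # independent oracle: solve rhs = 0 restricted to uniform states (A, a)
  p <- transport_params()
  f <- function(x) {
    st <- ring_state(rep(x[1], 5), rep(x[2], 5))
    d <- rhs_ring(st, p)
    c(d$dA[1], d$da[1])
  }
  x <- c(1, 1)
  for (it in 1:200) {
    h <- 1e-7
    J <- cbind((f(x + c(h, 0)) - f(x - c(h, 0))) / (2 * h),
               (f(x + c(0, h)) - f(x - c(0, h))) / (2 * h))
    step <- solve(J, -f(x))
    lam <- 1
    while (any(x + lam * step <= 0)) lam <- lam / 2
    x <- x + lam * step
    if (max(abs(f(x))) < 1e-12) break
  }
  ss <- homogeneous_steady_state(p)
  expect_equal(x[1], ss$A_star, tolerance = 1e-8)
  expect_equal(x[2], ss$a_star, tolerance = 1e-8)
})

test_that("state and parameter validation reject malformed input", {
  expect_error(ring_state(c(1, 2), c(1, 2, 3)), "same length")
  expect_error(ring_state(c(1, -2, 3), c(1, 2, 3)), ">= 0")
  expect_error(transport_params(rho = 0), "rho")
  expect_error(transport_params(I = -1), "I")
  expect_error(ring_geometry(2), ">= 3")
  expect_error(rhs_ring(structure(list(A = c(1, NaN, 1), a = rep(1, 3)),
                                  class = "ring_state"),
                        transport_params()), "non-finite")
})
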