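test_that("initial conditions implement the stated multiplicative noise law", {
  p <- transport_params()
  ss <- homogeneous_steady_state(p)
  # zero noise: exactly the fixed point
  st0 <- initial_state(p, 30, 0)
  expect_identical(st0$A, rep(ss$A_star, 30))
  expect_identical(st0$a, rep(ss$a_star, 30))
  # determinism under the seed
  expect_identical(initial_state(p, 30, 0.01, seed = 9),
                   initial_state(p, 30, 0.01, seed = 9))
  expect_false(identical(initial_state(p, 30, 0.01, seed = 9),
                         initial_state(p, 30, 0.01, seed = 10)))
  # Monte Carlo: mean of A_i is A*, spread matches uniform(-amp, amp)
  draws <- vapply(1:300, function(s)
    initial_state(p, 30, 0.05, seed = s)$A, numeric(30))
  se <- ss$A_star * 0.05 / sqrt(3) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - ss$A_star), 3 * se)
  expect_true(all(abs(draws - ss$A_star) <= 0.05 * ss$A_star + 1e-12))
})

test_that("compiled right-hand side agrees with the R reference", {
  set.seed(31)
  for (k in 1:5) {
    p <- random_params()
    N <- 17
    st <- ring_state(runif(N, 0.5, 25), runif(N, 0.1, 12))
    # one tiny RK4 step: the step quotient converges to the rhs
    dt <- 1e-9
    tr <- integrate_rk4(st, p, dt, dt)
    d <- rhs_ring(st, p)
    scale <- max(1, abs(c(d$dA, d$da)))
    expect_lt(max(abs((tr$final$A - st$A) / dt - d$dA)), 1e-5 * scale)
    expect_lt(max(abs((tr$final$a - st$a) / dt - d$da)), 1e-5 * scale)
  }
})

test_that("the integrator holds the homogeneous fixed point", {
  p <- transport_params()
  st <- initial_state(p, 60, 0)
  tr <- integrate_rk4(st, p, 1e-3, 2)
  expect_lt(max(abs(tr$final$A - st$A)), 1e-9)
  expect_lt(max(abs(tr$final$a - st$a)), 1e-9)
})

test_that("integration matches an independent fixed-step RK4 on a short
           horizon", {
  skip_if_not_installed("deSolve")
  p <- transport_params()
  st <- initial_state(p, 12, 0.01, seed = 4)
  f <- function(t, y, parms) {
    s <- ring_state(y[1:12], y[13:24])
    d <- rhs_ring(s, p)
    list(c(d$dA, d$da))
  }
  times <- seq(0, 0.02, by = 1e-3)
  ref <- deSolve::rk4(c(st$A, st$a), times, f, NULL)
  tr <- integrate_rk4(st, p, 1e-3, 0.02)
  expect_equal(tr$final$A, unname(ref[nrow(ref), 2:13]), tolerance = 1e-10)
  expect_equal(tr$final$a, unname(ref[nrow(ref), 14:25]), tolerance = 1e-10)
})

test_that("snapshots are recorded on the step grid", {
  p <- transport_params()
  st <- initial_state(p, 20, 0.01, seed = 2)
  tr <- integrate_rk4(st, p, 1e-3, 0.1, snapshot_times = c(0, 0.05, 0.1))
  expect_equal(tr$snapshot_times, c(0, 0.05, 0.1))
  expect_equal(dim(tr$snapshots$A), c(3, 20))
  expect_equal(unname(tr$snapshots$A[1, ]), st$A)
  expect_equal(unname(tr$snapshots$A[3, ]), tr$final$A)
  # off-grid times snap to the nearest step
  tr2 <- integrate_rk4(st, p, 1e-3, 0.1, snapshot_times = 0.0604)
  expect_equal(tr2$snapshot_times, 0.060)
  expect_error(integrate_rk4(st, p, 1e-3, 0.1, snapshot_times = 0.2),
               "beyond t_end")
})

test_that("integration aborts with diagnostics when the state diverges", {
  # gross step-size violation makes RK4 blow up
  p <- transport_params(E = 1e5, time_scale = 100)
  st <- initial_state(p, 12, 0.01, seed = 3)
  expect_error(integrate_rk4(st, p, 0.5, 50), "diverged at t")
})

test_that("ensembles are deterministic, seeded per replicate, and an
           ensemble of one reproduces a single integration", {
  cfg <- simulation_config(n_cells = 20, t_end = 0.5, dt = 1e-3,
                           n_replicates = 3, base_seed = 40L)
  e1 <- run_ensemble(cfg)
  e2 <- run_ensemble(cfg)
  expect_identical(e1$summaries, e2$summaries)
  expect_equal(e1$seeds, 41:43)
  expect_length(e1$failures, 0)
  cfg1 <- simulation_config(n_cells = 20, t_end = 0.5, dt = 1e-3,
                            n_replicates = 1, base_seed = 40L)
  single <- integrate_rk4(initial_state(cfg1$params, 20, 0.01, 41L),
                          cfg1$params, 1e-3, 0.5)
  expect_identical(run_ensemble(cfg1)$final_states[[1]]$A, single$final$A)
  expect_identical(run_ensemble(cfg1)$final_states[[1]]$a, single$final$a)
})

test_that("patterning parameters grow structure while stable parameters
           decay back to homogeneity", {
  # short-horizon amplitude movement on both sides of the boundary
  p_pat <- transport_params()                 # strongly unstable
  p_hom <- transport_params(I = 0.001, D = 50)  # strongly stable
  for (case in list(list(p = p_pat, grow = TRUE),
                    list(p = p_hom, grow = FALSE))) {
    st <- initial_state(case$p, 60, 0.01, seed = 8)
    amp0 <- summarize_pattern(st)$amplitude[1]
    tr <- integrate_rk4(st, case$p, 1e-4, 3)
    amp1 <- summarize_pattern(tr$final)$amplitude[1]
    if (case$grow) expect_gt(amp1, 2 * amp0) else expect_lt(amp1, amp0 / 2)
  }
})
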