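test_that("per-plant summaries satisfy the vascular-unit identity", {
  s <- section_measurement("p1", c(10, 10, 10, 10))
  expect_equal(unname(per_plant_summary(s)), c(4, 10, 40))
  s2 <- section_measurement("p2", c(8, 12))
  expect_equal(unname(per_plant_summary(s2)), c(2, 10, 20))
  set.seed(61)
  for (k in 1:20) {
    s <- section_measurement(k, sample(2:30, sample(2:12, 1), replace = TRUE))
    tr <- per_plant_summary(s)
    expect_equal(tr[["mean_lambda"]] * tr[["V"]], tr[["N_ring"]])
  }
  expect_error(section_measurement("x", integer(0)), "at least one")
  expect_error(section_measurement("x", c(3, 0)), "positive")
})

test_that("the worked spacing/cell-number decomposition recovers 66.67/33.33", {
  wt <- lapply(1:5, function(i) section_measurement(i, rep(10, 8)))
  mut <- lapply(1:5, function(i) section_measurement(i, rep(12, 6)))
  gc <- decompose_change(wt, mut)
  expect_equal(unname(gc$fractional), c(-0.2, -0.1))
  expect_equal(gc$contribution_spacing_pct, 200 / 3, tolerance = 1e-12)
  expect_equal(gc$contribution_cellnumber_pct, 100 / 3, tolerance = 1e-12)
  expect_equal(gc$contribution_spacing_pct + gc$contribution_cellnumber_pct,
               100)
  # identical groups: no net change, split undefined but flagged
  gc0 <- decompose_change(wt, wt)
  expect_true(gc0$undefined)
  expect_true(is.na(gc0$contribution_spacing_pct))
  expect_equal(unname(gc0$deltas), c(0, 0, 0))
})

test_that("contributions are invariant to group relabeling and to rescaling
           all counts", {
  set.seed(62)
  g1 <- make_cohort(8, 8, 10, 1, 1.5, seed = 3)
  g2 <- make_cohort(8, 6, 12, 1, 1.5, seed = 4)
  ab <- decompose_change(g1, g2)
  ba <- decompose_change(g2, g1)
  expect_equal(unname(ba$deltas[c("V", "N_ring")]),
               unname(-ab$deltas[c("V", "N_ring")]))
  # swapping labels changes the reference but the normalized split stays
  # the share of each effect in the total (both ratios change together)
  expect_equal(ab$contribution_spacing_pct + ab$contribution_cellnumber_pct,
               100)
  expect_equal(ba$contribution_spacing_pct + ba$contribution_cellnumber_pct,
               100)
  # common integer rescaling of all cell counts
  scale_units <- function(g, f) lapply(g, function(s)
    section_measurement(s$plant_id, s$unit_sizes * f))
  sc <- decompose_change(scale_units(g1, 3), scale_units(g2, 3))
  expect_equal(sc$contribution_spacing_pct, ab$contribution_spacing_pct,
               tolerance = 1e-12)
})

test_that("contribution percentages always sum to 100 when defined", {
  set.seed(63)
  for (k in 1:200) {
    g1 <- make_cohort(5, sample(4:10, 1), sample(6:14, 1), 1, 2, seed = k)
    g2 <- make_cohort(5, sample(4:10, 1), sample(6:14, 1), 1, 2,
                      seed = k + 1000)
    gc <- decompose_change(g1, g2)
    if (!gc$undefined) {
      tol <- 1e-9 * max(100, abs(gc$contribution_spacing_pct))
      expect_lt(abs(gc$contribution_spacing_pct +
                      gc$contribution_cellnumber_pct - 100), tol)
    }
  }
})

test_that("exact rank-sum p-values match enumeration and the classical
           example", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p_value, 0.1)
  expect_equal(w$method, "exact")
  # identical multisets: no separation, p = 1
  expect_equal(wilcoxon_rank_sum(c(2, 5, 5), c(2, 5, 5))$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "nonempty")
})

test_that("exact branch matches the bitmask permutation oracle, with and
           without ties", {
  set.seed(64)
  for (k in 1:120) {
    n <- sample(2:4, 1); m <- sample(2:5, 1)
    x <- sample(1:6, n, replace = TRUE)   # ties likely
    y <- sample(1:6, m, replace = TRUE)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, oracle_ranksum_p(x, y),
                 tolerance = 1e-12)
  }
  # untied cases also agree with the classical exact distribution
  for (k in 1:60) {
    n <- sample(3:5, 1); m <- sample(3:5, 1)
    v <- sample(1:100, n + m)
    x <- v[1:n]; y <- v[-(1:n)]
    ref <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, ref, tolerance = 1e-12)
  }
})

test_that("p-values are invariant under monotone transformation", {
  set.seed(65)
  x <- runif(6); y <- runif(8)
  p0 <- wilcoxon_rank_sum(x, y)$p_value
  expect_equal(wilcoxon_rank_sum(exp(x), exp(y))$p_value, p0)
  expect_equal(wilcoxon_rank_sum(x^3, y^3)$p_value, p0)
  # large samples switch to the tie-corrected normal approximation
  xl <- rnorm(20); yl <- rnorm(25) + 0.5
  w <- wilcoxon_rank_sum(xl, yl)
  expect_equal(w$method, "normal")
  ref <- stats::wilcox.test(xl, yl, exact = FALSE, correct = FALSE)$p.value
  expect_equal(w$p_value, ref, tolerance = 1e-10)
})

test_that("section CSV round-trips through the tidy per-unit schema", {
  groups <- list(wt = make_cohort(3, 8, 10, 0.5, 1, seed = 5),
                 mut = make_cohort(2, 6, 12, 0.5, 1, seed = 6))
  f <- tempfile(fileext = ".csv")
  write_sections_csv(groups, f)
  back <- read_sections_csv(f)
  expect_setequal(names(back), c("wt", "mut"))
  expect_equal(length(back$wt), 3)
  v0 <- vapply(groups$mut, function(s) s$V, numeric(1))
  v1 <- vapply(back$mut, function(s) s$V, numeric(1))
  expect_equal(sort(unname(v1)), sort(unname(v0)))
})
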