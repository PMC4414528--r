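#' One plant's vascular-ring morphometry
#'
#' A cross-section is decomposed into vascular units: each unit is the cells
#' of one vascular bundle (VB) plus the interfascicular fiber cells up to the
#' next VB. The unit sizes `lambda_k` (cells per unit) determine the bundle
#' count `V` (number of units) and the total provascular-ring cell count
#' `N_ring = sum(lambda_k)`, so `V = N_ring / mean(lambda)` by construction.
#'
#' @param plant_id identifier.
#' @param unit_sizes positive integer vector of vascular-unit sizes (cells).
#' @return An object of class `section_measurement` with fields `plant_id`,
#'   `V`, `unit_sizes`, `N_ring`.
#' @export
section_measurement <- function(plant_id, unit_sizes) {
  if (length(unit_sizes) == 0)
    stop("a section needs at least one vascular unit", call. = FALSE)
  if (any(unit_sizes <= 0) || any(unit_sizes != round(unit_sizes)))
    stop("unit sizes must be positive integers", call. = FALSE)
  structure(list(plant_id = plant_id, V = length(unit_sizes),
                 unit_sizes = as.integer(unit_sizes),
                 N_ring = sum(as.integer(unit_sizes))),
            class = "section_measurement")
}

#' Per-plant summary triple
#'
#' @param section a [section_measurement()].
#' @return named numeric vector `(V, mean_lambda, N_ring)`; the identity
#'   `mean_lambda * V = N_ring` holds exactly.
#' @export
per_plant_summary <- function(section) {
  stopifnot(inherits(section, "section_measurement"))
  c(V = section$V, mean_lambda = section$N_ring / section$V,
    N_ring = section$N_ring)
}

#' Wilcoxon rank-sum test with exact tie-aware enumeration
#'
#' Rank-sum (Mann-Whitney) test using midranks for ties. For combined sample
#' size `<= exact_limit` (default 12) the null distribution of the rank sum is
#' enumerated exactly over all assignments of ranks to the first sample;
#' otherwise a normal approximation with the usual tie correction (and no
#' continuity correction) is used. Two-sided p-values in the exact branch
#' count assignments at least as far from the null mean as observed, so two
#' identical samples give p = 1.
#'
#' @param x,y numeric samples (each nonempty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`,
#'   referring to the rank sum of `x`.
#' @param exact_limit switch point on `length(x) + length(y)`.
#' @return list with `statistic` (rank sum of `x`), `p_value`, and `method`
#'   (`"exact"` or `"normal"`).
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value  # exact, 0.1
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "less", "greater"),
                              exact_limit = 12) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be nonempty", call. = FALSE)
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))   # midranks
  W <- sum(r[seq_len(n)])
  mu <- n * (n + m + 1) / 2
  eps <- 1e-9
  if (n + m <= exact_limit) {
    combos <- utils::combn(n + m, n)
    Wall <- colSums(matrix(r[combos], nrow = n))
    p <- switch(alternative,
      two.sided = mean(abs(Wall - mu) >= abs(W - mu) - eps),
      less = mean(Wall <= W + eps),
      greater = mean(Wall >= W - eps))
    return(list(statistic = W, p_value = p, method = "exact"))
  }
  ties <- table(r)
  sigma2 <- n * m / 12 *
    ((n + m + 1) - sum(ties^3 - ties) / ((n + m) * (n + m - 1)))
  if (sigma2 <= 0)   # all observations tied
    return(list(statistic = W, p_value = 1, method = "normal"))
  z <- (W - mu) / sqrt(sigma2)
  p <- switch(alternative,
    two.sided = 2 * stats::pnorm(-abs(z)),
    less = stats::pnorm(z),
    greater = stats::pnorm(z, lower.tail = FALSE))
  list(statistic = W, p_value = min(p, 1), method = "normal")
}

#' Decompose a change in vascular-bundle number into spacing and cell-number
#' contributions
#'
#' The bundle count, unit size and ring cell count are tied by
#' `V = N / lambda`, so a change in `V` between two groups decomposes (to
#' first order, on group medians) into a spacing effect
#' `f_lambda = -delta(lambda) / lambda_ref` and a cell-number effect
#' `f_N = +delta(N) / N_ref`. The two are reported as percentages of their
#' sum, guaranteeing they add to 100%. The raw deltas, the unnormalized
#' ratios, and Wilcoxon rank-sum p-values for each per-plant variable
#' (`V`, mean unit size, `N_ring`) are also returned.
#'
#' @param reference list of [section_measurement()] (e.g. wild type).
#' @param comparison list of [section_measurement()] (e.g. mutant).
#' @param center `"median"` (default, used for the group summaries) or
#'   `"mean"` (accepted with a warning).
#' @return An object of class `group_comparison`: list with `medians`
#'   (2 x 3 matrix of group centers), `deltas`, `fractional` (named
#'   `f_lambda`, `f_N`), `contribution_spacing_pct`,
#'   `contribution_cellnumber_pct` (sum to 100 when defined), `undefined`
#'   (logical: `f_lambda + f_N == 0`), and `p_values`.
#' @export
#' @examples
#' wt <- lapply(1:5, function(i) section_measurement(i, rep(10, 8)))
#' mu <- lapply(1:5, function(i) section_measurement(i, rep(12, 6)))
#' decompose_change(wt, mu)
decompose_change <- function(reference, comparison,
                             center = c("median", "mean")) {
  center <- match.arg(center)
  if (center == "mean")
    warning("using group means; the standard summary is the median")
  cfun <- if (center == "median") stats::median else mean
  if (length(reference) == 0 || length(comparison) == 0)
    stop("both groups must be nonempty", call. = FALSE)
  tab <- function(group) {
    t(vapply(group, per_plant_summary, numeric(3)))
  }
  ref <- tab(reference); cmp <- tab(comparison)
  ctr <- rbind(reference = apply(ref, 2, cfun),
               comparison = apply(cmp, 2, cfun))
  deltas <- ctr["comparison", ] - ctr["reference", ]
  f_lambda <- -deltas[["mean_lambda"]] / ctr["reference", "mean_lambda"]
  f_N <- deltas[["N_ring"]] / ctr["reference", "N_ring"]
  denom <- f_lambda + f_N
  undefined <- denom == 0
  pv <- vapply(colnames(ref), function(v)
    wilcoxon_rank_sum(ref[, v], cmp[, v])$p_value, numeric(1))
  structure(list(
    medians = ctr,
    deltas = deltas,
    fractional = c(f_lambda = f_lambda, f_N = f_N),
    contribution_spacing_pct = if (undefined) NA_real_
                               else 100 * f_lambda / denom,
    contribution_cellnumber_pct = if (undefined) NA_real_
                                  else 100 * f_N / denom,
    undefined = undefined,
    p_values = pv,
    center = center
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  print(round(x$medians, 3))
  if (x$undefined) {
    cat("  no net change: contribution split undefined\n")
  } else {
    cat(sprintf("  spacing contribution: %.2f%%, cell-number contribution: %.2f%%\n",
                x$contribution_spacing_pct, x$contribution_cellnumber_pct))
  }
  cat("  Wilcoxon p-values:",
      paste(sprintf("%s = %.4g", names(x$p_values), x$p_values),
            collapse = ", "), "\n")
  invisible(x)
}

#' Read per-unit morphometry from a tidy CSV
#'
#' Expects columns `plant_id`, `group`, `unit_size` (one row per vascular
#' unit) and assembles one [section_measurement()] per plant, split by group.
#'
#' @param path CSV file path.
#' @return named list of lists of [section_measurement()], one per group.
#' @export
read_sections_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plant_id", "group", "unit_size")
  if (!all(need %in% names(df)))
    stop("CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  lapply(split(df, df$group), function(g) {
    lapply(split(g, g$plant_id), function(p)
      section_measurement(p$plant_id[1], p$unit_size))
  })
}
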