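# Synthetic-data generators. These emulate the two kinds of inputs the
# pipeline consumes — simulated ring auxin profiles with a known number of
# maxima, and per-plant vascular morphometry with planted group effects — so
# every quantification stage can be tested against ground truth without any
# external data.

#' Synthetic ring auxin profile with planted maxima
#'
#' Builds a circular profile as a sum of non-overlapping raised-cosine peaks
#' at `n_maxima` equally spaced positions over a flat base level, plus
#' optional Gaussian noise. A fraction of the peaks can be deliberately
#' shrunk so that their excess over the minima is about 5% of the main peak
#' height — safely below the 0.15 incipient-maxima rule — to exercise the
#' filter. Deterministic for a given seed.
#'
#' @param n_cells ring length.
#' @param n_maxima number of planted peaks (`<= n_cells / 2`).
#' @param base_level flat background (uM).
#' @param amplitude peak height above base (uM).
#' @param noise_sd Gaussian noise standard deviation (uM).
#' @param incipient_fraction fraction of the planted peaks to shrink below
#'   the filter threshold.
#' @param seed RNG seed (noise and choice of shrunk peaks).
#' @return list with `values`, `peak_idx` (all planted peaks), `full_idx`,
#'   `incipient_idx`, and the generating spec.
#' @export
#' @examples
#' pr <- make_ring_profile(60, 5, noise_sd = 0)
#' find_extrema(pr$values)$maxima
make_ring_profile <- function(n_cells, n_maxima, base_level = 1,
                              amplitude = 5, noise_sd = 0,
                              incipient_fraction = 0, seed = 1L) {
  if (n_maxima < 1 || n_maxima > n_cells / 2)
    stop("n_maxima must be in [1, n_cells/2]", call. = FALSE)
  if (base_level < 0 || amplitude < 0 || noise_sd < 0 ||
      incipient_fraction < 0 || incipient_fraction > 1)
    stop("all magnitudes must be nonnegative (fraction in [0,1])",
         call. = FALSE)
  k <- as.integer(n_maxima)
  pos <- floor((seq_len(k) - 1) * n_cells / k) + 1L
  half_width <- n_cells / (2 * k)
  n_inc <- round(incipient_fraction * k)
  with_seed(seed, {
    inc <- if (n_inc > 0) sort(sample(k, n_inc)) else integer(0)
    heights <- rep(amplitude, k)
    heights[inc] <- 0.05 * amplitude
    x <- seq_len(n_cells)
    values <- rep(base_level, n_cells)
    for (p in seq_len(k)) {
      d <- abs(x - pos[p])
      d <- pmin(d, n_cells - d)           # circular distance
      in_peak <- d < half_width
      values[in_peak] <- values[in_peak] +
        heights[p] * (1 + cos(pi * d[in_peak] / half_width)) / 2
    }
    if (noise_sd > 0) values <- values + stats::rnorm(n_cells, 0, noise_sd)
    list(values = values, peak_idx = pos,
         full_idx = pos[setdiff(seq_len(k), inc)],
         incipient_idx = pos[inc],
         spec = list(n_cells = n_cells, n_maxima = k,
                     base_level = base_level, amplitude = amplitude,
                     noise_sd = noise_sd,
                     incipient_fraction = incipient_fraction, seed = seed))
  })
}

#' Synthetic cohort of vascular cross-sections
#'
#' Generates `n_plants` plants: each draws a bundle count `V` and `V`
#' vascular-unit sizes from symmetric discretized (rounded normal)
#' distributions around the group medians, with unit sizes floored at 2 cells
#' and `V` at 1; `N_ring` is the sum of unit sizes, so the structural
#' identity `V = N_ring / mean(lambda)` holds by construction. With zero
#' dispersion every plant equals the medians exactly. Deterministic for a
#' given seed.
#'
#' @param n_plants cohort size.
#' @param median_V group median bundle count.
#' @param median_lambda group median unit size (cells).
#' @param dispersion_V,dispersion_lambda standard deviations of the
#'   discretized draws.
#' @param seed RNG seed.
#' @return list of [section_measurement()].
#' @export
#' @examples
#' make_cohort(3, median_V = 8, median_lambda = 10)
make_cohort <- function(n_plants, median_V = 8, median_lambda = 10,
                        dispersion_V = 0, dispersion_lambda = 0,
                        seed = 1L) {
  if (n_plants < 1) stop("n_plants must be >= 1", call. = FALSE)
  if (median_V <= 0 || median_lambda <= 0)
    stop("medians must be > 0", call. = FALSE)
  with_seed(seed, {
    lapply(seq_len(n_plants), function(i) {
      V <- max(1L, as.integer(round(median_V +
                                      stats::rnorm(1) * dispersion_V)))
      lam <- pmax(2L, as.integer(round(median_lambda +
                                         stats::rnorm(V) * dispersion_lambda)))
      section_measurement(plant_id = i, unit_sizes = lam)
    })
  })
}

#' Write a synthetic cohort as the tidy per-unit CSV schema
#'
#' @param groups named list of cohorts (lists of [section_measurement()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sections_csv <- function(groups, path) {
  rows <- do.call(rbind, lapply(names(groups), function(g) {
    do.call(rbind, lapply(groups[[g]], function(s)
      data.frame(plant_id = s$plant_id, group = g,
                 unit_size = s$unit_sizes)))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
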