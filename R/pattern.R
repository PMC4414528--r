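#' Local extrema on a periodic ring
#'
#' Finds strict local maxima and minima of a circular profile. A flat plateau
#' strictly above (below) both flanking values counts once, at its lowest
#' member index. A constant ring has no extrema. Before any filtering, maxima
#' and minima alternate around the ring and their counts are equal.
#'
#' @param values numeric vector (length >= 3), circular.
#' @return list with integer index vectors `maxima` and `minima` (1-based).
#' @export
#' @examples
#' find_extrema(c(5, 1, 1, 5, 1, 1))
find_extrema <- function(values) {
  values <- unname(as.numeric(values))
  n <- length(values)
  if (n < 3) stop("ring must have at least 3 entries", call. = FALSE)
  if (!all(is.finite(values))) stop("non-finite values", call. = FALSE)
  if (all(values == values[1])) return(list(maxima = integer(0),
                                            minima = integer(0)))
  # rotate so position 1 starts a new run, making run-compression linear
  brk <- which(values != c(values[n], values[-n]))[1]
  rot <- if (brk == 1) values else c(values[brk:n], values[1:(brk - 1)])
  r <- rle(rot)
  k <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- c(1L, ends[-k] + 1L)
  prev <- r$values[c(k, seq_len(k - 1))]
  nxt <- r$values[c(seq_len(k - 1) + 1L, 1L)]
  is_max <- r$values > prev & r$values > nxt
  is_min <- r$values < prev & r$values < nxt
  # lowest original index of each run (runs never span the wrap after rotation
  # in rotated coordinates, but may contain original index 1 region)
  orig_idx <- function(run) {
    pos <- starts[run]:ends[run]
    min((pos + brk - 2L) %% n + 1L)
  }
  list(maxima = sort(vapply(which(is_max), orig_idx, integer(1))),
       minima = sort(vapply(which(is_min), orig_idx, integer(1))))
}

#' Filter incipient maxima
#'
#' Implements the incipient-maxima rule: the provisional pattern amplitude is
#' computed from all detected extrema (mean of maxima values minus mean of
#' minima values); a maximum is omitted when its excess over the average
#' minima is less than `threshold` (default 0.15) times that provisional
#' amplitude. Minima are never filtered. Reported statistics are then
#' recomputed on the retained maxima only.
#'
#' @param values the ring profile.
#' @param maxima,minima index vectors from [find_extrema()].
#' @param threshold fraction of the provisional amplitude below which a
#'   maximum counts as incipient (0 disables the filter).
#' @return list with `retained` and `removed` maxima index vectors and
#'   logical `degenerate` (no minima to measure against).
#' @export
filter_incipient <- function(values, maxima, minima, threshold = 0.15) {
  if (length(minima) == 0 || length(maxima) == 0)
    return(list(retained = integer(0), removed = maxima,
                degenerate = TRUE))
  avg_min <- mean(values[minima])
  amp_prov <- mean(values[maxima]) - avg_min
  keep <- (values[maxima] - avg_min) >= threshold * amp_prov
  list(retained = maxima[keep], removed = maxima[!keep], degenerate = FALSE)
}

# core statistics for one circular profile
summarize_profile <- function(values, threshold = 0.15) {
  ex <- find_extrema(values)
  fl <- filter_incipient(values, ex$maxima, ex$minima, threshold)
  n <- length(values)
  retained <- fl$retained
  avg_max <- if (length(retained)) mean(values[retained]) else NA_real_
  avg_min <- if (length(ex$minima)) mean(values[ex$minima]) else NA_real_
  amplitude <- if (length(retained) && length(ex$minima))
    avg_max - avg_min else 0
  data.frame(
    n_maxima = length(retained),
    n_incipient_removed = length(fl$removed),
    kappa_sim = length(retained) / n,
    amplitude = amplitude,
    avg_max = avg_max,
    avg_min = avg_min,
    mean_level = mean(values)
  )
}

#' Pattern statistics of a ring state
#'
#' Applies peak detection and the incipient-maxima filter independently to
#' the cytosolic and apoplastic profiles and reports, per compartment: the
#' simulated wavenumber `kappa_sim` (retained maxima over cells), the pattern
#' amplitude (average retained-maxima level minus average minima level), the
#' average maxima and minima levels, and the ring mean. A homogeneous state
#' yields `kappa_sim = 0` and zero amplitude.
#'
#' @param state a [ring_state()], or a plain numeric vector (treated as a
#'   single unnamed compartment).
#' @param threshold incipient-maxima threshold, default 0.15.
#' @return data.frame with one row per compartment (`cyto`, `apo`) and
#'   columns `compartment`, `n_maxima`, `n_incipient_removed`, `kappa_sim`,
#'   `amplitude`, `avg_max`, `avg_min`, `mean_level`.
#' @export
#' @examples
#' st <- ring_state(5 + cos(2 * pi * 5 * (0:59) / 60), rep(1, 60))
#' summarize_pattern(st)
summarize_pattern <- function(state, threshold = 0.15) {
  if (is.numeric(state)) {
    out <- summarize_profile(state, threshold)
    out <- cbind(compartment = "profile", out)
    return(out)
  }
  stopifnot(inherits(state, "ring_state"))
  cyto <- summarize_profile(state$A, threshold)
  apo <- summarize_profile(state$a, threshold)
  cbind(compartment = c("cyto", "apo"), rbind(cyto, apo))
}
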