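# Independent oracles used across test files. Each reimplements the checked
# quantity by a different mechanism than the package code.

# Brute-force circular extrema: for every position, walk to the nearest
# differing value on each side; plateaus count once at their lowest index.
oracle_extrema <- function(v) {
  n <- length(v)
  if (all(v == v[1])) return(list(maxima = integer(0), minima = integer(0)))
  walk <- function(i, step) {
    j <- i
    repeat {
      j <- (j - 1 + step) %% n + 1
      if (v[j] != v[i]) return(v[j])
    }
  }
  kind <- vapply(seq_len(n), function(i) {
    l <- walk(i, -1); r <- walk(i, 1)
    if (v[i] > l && v[i] > r) 1L else if (v[i] < l && v[i] < r) -1L else 0L
  }, integer(1))
  canonical <- function(i) {
    # lowest original index of the plateau containing i
    members <- i
    j <- i
    repeat {
      j <- (j - 2) %% n + 1
      if (v[j] != v[i] || j == i) break
      members <- c(members, j)
    }
    j <- i
    repeat {
      j <- j %% n + 1
      if (v[j] != v[i] || j == i) break
      members <- c(members, j)
    }
    as.integer(min(members))
  }
  list(maxima = sort(unique(vapply(which(kind == 1L), canonical, integer(1)))),
       minima = sort(unique(vapply(which(kind == -1L), canonical, integer(1)))))
}

# Central finite-difference Jacobian of the reference R right-hand side.
fd_jacobian <- function(params, state) {
  N <- length(state$A)
  x0 <- c(state$A, state$a)
  f <- function(x) {
    s <- ring_state(pmax(x[1:N], 0), pmax(x[N + 1:N], 0))
    r <- rhs_ring(s, params)
    c(r$dA, r$da)
  }
  h <- 1e-6 * max(max(x0), 1)
  vapply(seq_along(x0), function(j) {
    e <- numeric(2 * N); e[j] <- h
    (f(x0 + e) - f(x0 - e)) / (2 * h)
  }, numeric(2 * N))
}

# Exact rank-sum p-value by bitmask subset enumeration (independent of the
# combn-based implementation path).
oracle_ranksum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)])
  mu <- n * (n + m + 1) / 2
  tot <- n + m
  Wall <- c()
  for (mask in 0:(2^tot - 1)) {
    bits <- as.integer(intToBits(mask)[1:tot])
    if (sum(bits) == n) Wall <- c(Wall, sum(r[bits == 1L]))
  }
  mean(abs(Wall - mu) >= abs(W - mu) - 1e-9)
}

# random valid transport parameter draw over wide log-uniform ranges
random_params <- function() {
  theta <- function() if (stats::runif(1) < 0.2) 0 else stats::runif(1, 1, 20)
  transport_params(
    I = 10^stats::runif(1, -3, 2.3),
    E = 10^stats::runif(1, -1, 2.3),
    D = 10^stats::runif(1, -2, 1.7),
    D_ca = 10^stats::runif(1, 0, 1.7),
    sigma_c = stats::runif(1, 0.5, 20),
    nu_c = stats::runif(1, 0.05, 2),
    theta_I = theta(), theta_P = theta(),
    rho = 10^stats::runif(1, -0.5, 1),
    w = stats::runif(1, 0.5, 2),
    polarity_exponent = sample(1:2, 1),
    time_scale = sample(c(0.5, 1), 1)
  )
}

rotate_ring <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) x else c(x[(k + 1):n], x[1:k])
}

max_abs_rhs <- function(params, state) {
  d <- rhs_ring(state, params)
  max(abs(c(d$dA, d$da)))
}
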