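#' Attractor state of a network
#'
#' A settled network state: the rate vector plus the binary UP/DOWN
#' signature per pair.  Pair i is UP iff its excitatory rate exceeds `eps`
#' (0.1 Hz, matching the fixed-point radius; DOWN units sit exactly at zero
#' in the rectified model).  Two states are equal iff their signatures match
#' and their rate vectors agree within 0.1 Hz in max-norm.
#'
#' @param rates Length-2N rate vector (Hz).
#' @param n_pairs Number of pairs N.
#' @param is_timeout Did settling hit the time cap?
#' @param settle_time Settling time (ms), if known.
#' @param eps UP threshold on the excitatory rate (Hz).
#' @return An object of class `attractor_state`.
#' @export
attractor_state <- function(rates, n_pairs = length(rates) %/% 2L,
                            is_timeout = FALSE, settle_time = NA_real_,
                            eps = 0.1) {
  rates <- as.numeric(rates)
  structure(list(rates = rates,
                 signature = rates[e_indices(n_pairs)] > eps,
                 is_timeout = isTRUE(is_timeout),
                 settle_time = settle_time),
            class = "attractor_state")
}

signature_string <- function(state) {
  paste(as.integer(state$signature), collapse = "")
}

#' @export
print.attractor_state <- function(x, ...) {
  cat(sprintf("attractor_state [%s]%s  rates: %s\n", signature_string(x),
              if (x$is_timeout) " (timeout)" else "",
              paste(sprintf("%.3g", x$rates), collapse = " ")))
  invisible(x)
}

states_equal <- function(a, b, tol = 0.1) {
  identical(a$signature, b$signature) && max(abs(a$rates - b$rates)) < tol
}

# find the index of `state` in a list of states, 0 if absent
match_state <- function(state, states, tol = 0.1) {
  for (i in seq_along(states))
    if (states_equal(state, states[[i]], tol)) return(i)
  0L
}

# initial rate vector for a given UP/DOWN pattern and UP-rate guess
pattern_start <- function(pattern, up_rates, n_pairs) {
  r <- numeric(2L * n_pairs)
  up <- which(pattern)
  r[2L * up - 1L] <- up_rates[1]
  r[2L * up] <- up_rates[2]
  r
}

# the three UP-rate guesses: the isolated-pair closed form, half, and double
up_rate_guesses <- function(spec) {
  fp <- fixed_point_up(spec$pair)
  base <- c(fp$r_e, fp$r_i)
  list(base, 0.5 * base, 2 * base)
}

#' Enumerate the point attractors of a network
#'
#' Settles the network from 3 * 2^N initial conditions: every UP/DOWN
#' pattern over the N pairs, each with three guesses for the UP rates (the
#' isolated-pair fixed point, half it, and double it, bracketing
#' coupling-shifted UP states).  Unique settled states are collected;
#' timeouts are excluded from the count and reported.
#'
#' @param matrix Weight matrix from [build_weight_matrix()].
#' @param spec The `network_spec`.
#' @param dt Integration step (ms).
#' @param max_time Settling cap per start (ms).
#' @param n_max Guard on N (3 * 2^N settles).
#' @return A list of class `attractor_set`: `states` (list of
#'   `attractor_state`), `count`, `n_timeouts`, `unreliable` (more than 1%
#'   of settles timed out).
#' @export
enumerate_attractors <- function(matrix, spec = attr(matrix, "spec"),
                                 dt = 0.01, max_time = 12000, n_max = 14L) {
  n <- spec$n_pairs
  if (n > n_max)
    stop("N = ", n, " exceeds the 3 * 2^N enumeration guard (", n_max, ")",
         call. = FALSE)
  guesses <- up_rate_guesses(spec)
  states <- list()
  n_timeouts <- 0L
  n_settles <- 0L
  for (code in 0:(2^n - 1)) {
    pattern <- as.logical(bitwAnd(bitwShiftR(code, 0:(n - 1L)), 1L))
    for (g in guesses) {
      st <- settle(matrix, spec, pattern_start(pattern, g, n),
                   max_time = max_time, dt = dt)
      n_settles <- n_settles + 1L
      if (st$is_timeout) { n_timeouts <- n_timeouts + 1L; next }
      if (match_state(st, states) == 0L) states[[length(states) + 1L]] <- st
    }
  }
  structure(list(states = states, count = length(states),
                 n_timeouts = n_timeouts,
                 unreliable = n_timeouts > 0.01 * n_settles),
            class = "attractor_set")
}

#' @export
print.attractor_set <- function(x, ...) {
  cat(sprintf("attractor_set: %d states, %d timeouts%s\n", x$count,
              x$n_timeouts, if (isTRUE(x$unreliable)) " (UNRELIABLE)" else ""))
  invisible(x)
}

# is every cross-class of the matrix homogeneous (identical entries)?
is_homogeneous_matrix <- function(matrix, spec = attr(matrix, "spec"),
                                  tol = 1e-12) {
  n <- spec$n_pairs
  if (n == 1L) return(TRUE)
  W <- unclass(matrix)
  for (row in seq_len(2L * n)) {
    pr <- (row + 1L) %/% 2L
    for (cols in list(e_indices(n), i_indices(n))) {
      cc <- cols[(cols + 1L) %/% 2L != pr]
      if (length(cc) > 1L && diff(range(W[row, cc])) > tol) return(FALSE)
    }
  }
  TRUE
}

#' Count attractors of a homogeneous network in O(N) settles
#'
#' For a network whose cross-connections are identical within each class
#' (cv = 0), every pair is interchangeable: if one pattern with k pairs UP
#' is stable, all choose(N, k) permutations are.  It therefore suffices to
#' settle one representative pattern per k = 0..N (three UP-rate guesses
#' each, 3(N+1) settles) and credit each stable k-class with its binomial
#' multiplicity.
#'
#' @inheritParams enumerate_attractors
#' @return An `attractor_set` whose `states` are the unique representative
#'   states, each with an attached `multiplicity` attribute; `count` is the
#'   multiplicity-weighted total.
#' @export
enumerate_attractors_homogeneous <- function(matrix,
                                             spec = attr(matrix, "spec"),
                                             dt = 0.01, max_time = 12000) {
  if (!is_homogeneous_matrix(matrix, spec))
    stop("matrix is not homogeneous: cross-connections differ within a class",
         call. = FALSE)
  n <- spec$n_pairs
  guesses <- up_rate_guesses(spec)
  states <- list()
  n_timeouts <- 0L
  n_settles <- 0L
  for (k in 0:n) {
    pattern <- seq_len(n) <= k
    for (g in guesses) {
      st <- settle(matrix, spec, pattern_start(pattern, g, n),
                   max_time = max_time, dt = dt)
      n_settles <- n_settles + 1L
      if (st$is_timeout) { n_timeouts <- n_timeouts + 1L; next }
      if (match_state(st, states) == 0L) states[[length(states) + 1L]] <- st
    }
  }
  total <- 0
  for (i in seq_along(states)) {
    k_up <- sum(states[[i]]$signature)
    mult <- choose(n, k_up)
    attr(states[[i]], "multiplicity") <- mult
    total <- total + mult
  }
  structure(list(states = states, count = total,
                 n_timeouts = n_timeouts,
                 unreliable = n_timeouts > 0.01 * n_settles),
            class = "attractor_set")
}

#' Fit exponential growth of attractor count with network size
#'
#' Nonlinear least squares of `y = a * b^x + c` to (network size, state
#' count) data, with the deterministic initialization a = 1, b = 2, c = 0.
#'
#' @param sizes Network sizes N (>= 4 distinct values).
#' @param counts Attractor counts.
#' @return A list of class `growth_fit`: `a`, `b`, `c`, `residual_norm`.
#' @export
fit_state_growth <- function(sizes, counts) {
  if (length(unique(sizes)) < 4L)
    stop("need at least 4 distinct sizes to fit exponential growth",
         call. = FALSE)
  df <- data.frame(x = as.numeric(sizes), y = as.numeric(counts))
  fit <- tryCatch(
    stats::nls(y ~ a * b^x + c, data = df,
               start = list(a = 1, b = 2, c = 0),
               algorithm = "port", lower = c(a = 1e-8, b = 1e-8, c = -Inf),
               control = stats::nls.control(maxiter = 500, warnOnly = FALSE)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # deterministic fallback: direct least squares on the same residuals
    obj <- function(p) sum((df$y - p[1] * p[2]^df$x - p[3])^2)
    op <- stats::optim(c(1, 2, 0), obj, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-12))
    if (op$value > sum(df$y^2))
      stop("growth fit failed to converge; residual norm ", sqrt(op$value),
           call. = FALSE)
    p <- op$par
    return(structure(list(a = p[1], b = abs(p[2]), c = p[3],
                          residual_norm = sqrt(op$value)),
                     class = "growth_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"]),
                 residual_norm = sqrt(sum(stats::resid(fit)^2))),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("growth_fit: y = %.4g * %.4g^x + %.4g  (residual norm %.3g)\n",
              x$a, x$b, x$c, x$residual_norm))
  invisible(x)
}
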