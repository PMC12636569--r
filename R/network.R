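#' Cross-connectivity statistics
#'
#' Magnitude statistics for the four classes of weak random cross-pair
#' connections.  Class names follow the weight naming of [isp_params()]:
#' `ee` = E source onto E target, `ie` = I source onto E target, etc.
#' Each class carries a mean and either an sd or a coefficient of variation
#' (cv = sd/mean) of the *magnitude* of the sampled weights; Dale's law
#' signs are applied afterwards.
#'
#' @param mean_ee,mean_ie,mean_ei,mean_ii Class mean magnitudes (>= 0).
#' @param cv Shared coefficient of variation (sd = cv * mean), or
#' @param sd_ee,sd_ie,sd_ei,sd_ii explicit per-class sds (override `cv`).
#' @return A named list of class `cross_stats`.
#' @export
cross_stats <- function(mean_ee, mean_ie, mean_ei, mean_ii, cv = 0,
                        sd_ee = NULL, sd_ie = NULL, sd_ei = NULL,
                        sd_ii = NULL) {
  means <- c(ee = mean_ee, ie = mean_ie, ei = mean_ei, ii = mean_ii)
  if (any(means < 0)) stop("cross-connection means must be >= 0", call. = FALSE)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  sds <- c(ee = if (is.null(sd_ee)) cv * mean_ee else sd_ee,
           ie = if (is.null(sd_ie)) cv * mean_ie else sd_ie,
           ei = if (is.null(sd_ei)) cv * mean_ei else sd_ei,
           ii = if (is.null(sd_ii)) cv * mean_ii else sd_ii)
  if (any(sds < 0)) stop("cross-connection sds must be >= 0", call. = FALSE)
  structure(lapply(c("ee", "ie", "ei", "ii"), function(cl)
    list(mean = unname(means[cl]), sd = unname(sds[cl]))) |>
      stats::setNames(c("ee", "ie", "ei", "ii")),
    class = "cross_stats")
}

#' Fiducial cross-connectivity derived from a pair
#'
#' Convenience constructor: class mean magnitudes proportional to the
#' corresponding within-pair weight magnitudes (`frac` of each), preserving
#' the E/I balance of the pair while keeping cross-connections weak.
#'
#' @param pair An `isp_params` object.
#' @param frac Fraction of the within-pair magnitude (default 0.1).
#' @param cv Coefficient of variation of the magnitudes (default 0.5).
#' @return A `cross_stats` object.
#' @export
fiducial_cross_stats <- function(pair, frac = 0.1, cv = 0.5) {
  cross_stats(mean_ee = frac * abs(pair$w_ee),
              mean_ie = frac * abs(pair$w_ie),
              mean_ei = frac * abs(pair$w_ei),
              mean_ii = frac * abs(pair$w_ii),
              cv = cv)
}

#' Network specification
#'
#' Describes an inhibition-stabilized network of `n_pairs` identical
#' bistable pairs coupled all-to-all by weak random cross-connections.
#'
#' @param n_pairs Number N of E-I pairs (>= 1).
#' @param pair Within-pair parameters (`isp_params`), identical for every
#'   pair.
#' @param cross_stats Cross-connection magnitude statistics
#'   ([cross_stats()]).
#' @param cross_family Sampling family for cross magnitudes, `"lognormal"`
#'   or `"gamma"`.
#' @param scale_with_n If `TRUE` (default), realized cross means and sds are
#'   the base values divided by N, keeping the mean total input per unit
#'   constant as the network grows.
#' @param tau Rate time constant in ms (default 10).
#' @param seed Integer RNG seed; identical specs yield bit-identical
#'   matrices.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(n_pairs, pair, cross_stats = NULL,
                         cross_family = c("lognormal", "gamma"),
                         scale_with_n = TRUE, tau = 10, seed = 1L) {
  cross_family <- match.arg(cross_family)
  if (!inherits(pair, "isp_params")) stop("'pair' must be an isp_params object",
                                          call. = FALSE)
  if (n_pairs < 1) stop("n_pairs must be >= 1", call. = FALSE)
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (is.null(cross_stats)) cross_stats <- cross_stats(0, 0, 0, 0)
  if (!inherits(cross_stats, "cross_stats"))
    stop("'cross_stats' must be built with cross_stats()", call. = FALSE)
  structure(list(n_pairs = as.integer(n_pairs), pair = pair,
                 cross_stats = cross_stats, cross_family = cross_family,
                 scale_with_n = isTRUE(scale_with_n), tau = tau,
                 seed = as.integer(seed)),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("network_spec: N = %d pairs (%d units), tau = %g ms, seed = %d\n",
              x$n_pairs, 2L * x$n_pairs, x$tau, x$seed))
  cat(sprintf("  cross family: %s%s\n", x$cross_family,
              if (x$scale_with_n) " (1/N scaled)" else ""))
  for (cl in names(x$cross_stats))
    cat(sprintf("  cross %s: mean %.4g, sd %.4g\n", cl,
                x$cross_stats[[cl]]$mean, x$cross_stats[[cl]]$sd))
  invisible(x)
}

# unit bookkeeping: unit 2i-1 is the excitatory and 2i the inhibitory member
# of pair i (i = 1..N); labels use the 0-based convention E0, I0, E1, ...
unit_labels <- function(n_pairs) {
  as.vector(rbind(paste0("E", seq_len(n_pairs) - 1L),
                  paste0("I", seq_len(n_pairs) - 1L)))
}

e_indices <- function(n_pairs) seq(1L, 2L * n_pairs, by = 2L)
i_indices <- function(n_pairs) seq(2L, 2L * n_pairs, by = 2L)

theta_vector <- function(spec) {
  rep(c(spec$pair$theta_e, spec$pair$theta_i), spec$n_pairs)
}

# evaluate code under a temporary RNG state so package functions never
# disturb the caller's stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a stable sub-seed (< 2^31) from a base seed and a component label
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 2654435761 + h * 97 + 1) %% 2147483647)
}

# sample n cross magnitudes and affine-rescale so the realized mean and
# (sample) sd match the targets exactly; negative excursions are floored at
# 1e-12 and the mean restored multiplicatively (sd then approximate).
sample_matched <- function(n, m, s, family) {
  if (n == 0L) return(numeric(0))
  if (m == 0) {
    if (s > 0) stop("infeasible cross stats: sd > 0 with zero mean",
                    call. = FALSE)
    return(rep(0, n))
  }
  if (s == 0) return(rep(m, n))
  if (n == 1L)
    stop("infeasible cross stats: sd > 0 requested with a single cross partner",
         call. = FALSE)
  x <- switch(family,
    lognormal = {
      sdlog <- sqrt(log1p((s / m)^2))
      stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
    },
    gamma = {
      shape <- (m / s)^2            # shape = 1/cv^2
      stats::rgamma(n, shape = shape, rate = shape / m)
    },
    stop("unknown cross family: ", family, call. = FALSE))
  y <- m + (x - mean(x)) * s / stats::sd(x)
  if (any(y < 0)) {
    y <- pmax(y, 1e-12)
    y <- y * (m / mean(y))
  }
  y
}

#' Build the constrained random weight matrix of a network
#'
#' Assembles the 2N x 2N signed weight matrix: identical within-pair blocks
#' from `spec$pair` on the diagonal, and random cross-pair weights sampled
#' row by row from the configured family, with every row's per-class mean
#' and sd matched to the specification exactly (so the input statistics of
#' every unit are identical).  Dale's law is enforced by sign convention:
#' columns of excitatory units are >= 0, columns of inhibitory units <= 0.
#' Entry (i, j) is the weight from unit j onto unit i.
#'
#' @param spec A `network_spec`.
#' @return A matrix of class `isn_weight_matrix` with unit labels
#'   `E0, I0, E1, ...` and the generating spec attached as attribute
#'   `"spec"`.
#' @export
build_weight_matrix <- function(spec) {
  n <- spec$n_pairs
  p <- spec$pair
  labels <- unit_labels(n)
  W <- matrix(0, 2L * n, 2L * n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    idx <- c(2L * i - 1L, 2L * i)
    W[idx, idx] <- matrix(c(p$w_ee, p$w_ie, p$w_ei, p$w_ii), 2, byrow = TRUE)
  }
  if (n > 1L) {
    scale <- if (spec$scale_with_n) n else 1L
    eidx <- e_indices(n); iidx <- i_indices(n)
    with_seed(spec$seed, {
      for (row in seq_len(2L * n)) {
        pair_of_row <- (row + 1L) %/% 2L
        target_is_e <- row %% 2L == 1L
        for (src_type in c("e", "i")) {
          cl <- paste0(src_type, if (target_is_e) "e" else "i")
          st <- spec$cross_stats[[cl]]
          cols <- if (src_type == "e") eidx else iidx
          cols <- cols[(cols + 1L) %/% 2L != pair_of_row]
          mags <- sample_matched(length(cols), st$mean / scale,
                                 st$sd / scale, spec$cross_family)
          W[row, cols] <- if (src_type == "e") mags else -mags
        }
      }
    })
  }
  structure(W, class = c("isn_weight_matrix", "matrix", "array"), spec = spec)
}

#' Family of heterogeneous weight matrices over a cv sweep
#'
#' For each coefficient of variation and replicate, build a matrix whose
#' cross-weight magnitudes follow a gamma distribution with the spec's class
#' means and the given cv, keeping the mean input to every unit identical
#' across the whole family.
#'
#' @param spec A `network_spec`; its class means are reused, its
#'   `cross_family` is overridden to gamma.
#' @param cv_values Non-negative coefficients of variation.
#' @param replicates Matrices per cv value.
#' @return A list with one element per (cv, replicate), each a
#'   `isn_weight_matrix`; attributes `cv` and `replicate` identify the cell.
#' @export
build_heterogeneous_family <- function(spec, cv_values, replicates = 1L) {
  if (any(cv_values < 0)) stop("cv values must be >= 0", call. = FALSE)
  out <- list()
  for (ci in seq_along(cv_values)) {
    cv <- cv_values[ci]
    for (rep_i in seq_len(replicates)) {
      st <- spec$cross_stats
      st_cv <- cross_stats(st$ee$mean, st$ie$mean, st$ei$mean, st$ii$mean,
                           cv = cv)
      sp <- network_spec(spec$n_pairs, spec$pair, st_cv,
                         cross_family = "gamma",
                         scale_with_n = spec$scale_with_n, tau = spec$tau,
                         seed = derive_seed(spec$seed,
                                            sprintf("hetero-%d-%d", ci, rep_i)))
      m <- build_weight_matrix(sp)
      attr(m, "cv") <- cv
      attr(m, "replicate") <- rep_i
      out[[length(out) + 1L]] <- m
    }
  }
  out
}

#' Rectangular current pulse
#'
#' A stimulus is a shared scalar current I(t) = amplitude on
#' `[onset, onset + duration)`, delivered to unit a with gain `weights[a]`.
#' Weight vectors have unit mean; the default (uniform ones) delivers the
#' identical current to every unit, excitatory and inhibitory alike.
#'
#' @param amplitude Pulse amplitude (input-current units).
#' @param duration Pulse duration (ms), > 0.
#' @param onset Pulse onset time (ms).
#' @param weights Optional length-2N per-unit weight vector with unit mean;
#'   `NULL` means uniform.
#' @return An object of class `stimulus_pulse`.
#' @export
stimulus_pulse <- function(amplitude, duration, onset = 0, weights = NULL) {
  if (duration <= 0) stop("stimulus duration must be > 0", call. = FALSE)
  if (!is.null(weights)) {
    if (abs(mean(weights) - 1) > 1e-9)
      stop("stimulus weight vector must have unit mean", call. = FALSE)
  }
  structure(list(amplitude = amplitude, duration = duration, onset = onset,
                 weights = weights),
            class = "stimulus_pulse")
}

stim_arrays <- function(stimuli, n_units) {
  if (length(stimuli) == 0L)
    return(list(amp = numeric(0), onset = numeric(0), dur = numeric(0),
                wts = matrix(0, n_units, 0)))
  if (inherits(stimuli, "stimulus_pulse")) stimuli <- list(stimuli)
  amp <- vapply(stimuli, `[[`, numeric(1), "amplitude")
  onset <- vapply(stimuli, `[[`, numeric(1), "onset")
  dur <- vapply(stimuli, `[[`, numeric(1), "duration")
  wts <- vapply(stimuli, function(s) {
    if (is.null(s$weights)) rep(1, n_units)
    else {
      if (length(s$weights) != n_units)
        stop("stimulus weight vector length must be 2N", call. = FALSE)
      s$weights
    }
  }, numeric(n_units))
  list(amp = amp, onset = onset, dur = dur,
       wts = matrix(wts, nrow = n_units))
}

#' Integrate the network rate equation
#'
#' Classical fourth-order Runge-Kutta on
#' `tau * dr/dt = -r + W.r - theta + sum_a w_a I_a(t)` with the
#' threshold-linear nonlinearity enforced by rectifying the state inside
#' every stage evaluation and clamping to zero after every full step.
#'
#' @param matrix A weight matrix from [build_weight_matrix()].
#' @param spec The `network_spec` (for `tau` and thresholds); defaults to
#'   the spec attached to `matrix`.
#' @param initial Length-2N vector of initial rates (>= 0).
#' @param stimuli A `stimulus_pulse` or list thereof (may be empty).
#' @param t_end Integration horizon (ms).
#' @param dt Step size (ms), default 0.01.
#' @param record_every Store every k-th step (default chosen so ~<= 2000
#'   samples are kept); endpoints are exact step values.
#' @return A list of class `isn_trajectory` with `times` (ms), `rates`
#'   (time x unit matrix, Hz), `final` and `dt`.
#' @export
simulate <- function(matrix, spec = attr(matrix, "spec"), initial,
                     stimuli = list(), t_end, dt = 0.01,
                     record_every = NULL) {
  n_units <- nrow(matrix)
  if (length(initial) != n_units) stop("initial must have length 2N",
                                       call. = FALSE)
  if (any(initial < 0)) stop("initial rates must be >= 0", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (is.null(record_every))
    record_every <- max(1L, as.integer(ceiling(t_end / dt / 2000)))
  sa <- stim_arrays(stimuli, n_units)
  res <- .rk4_integrate(unclass(matrix), theta_vector(spec), spec$tau,
                        as.numeric(initial), sa$amp, sa$onset, sa$dur,
                        sa$wts, t_end, dt, as.integer(record_every))
  rates <- res$rates
  colnames(rates) <- unit_labels(spec$n_pairs)
  structure(list(times = as.numeric(res$times), rates = rates,
                 final = as.numeric(res$final), dt = dt),
            class = "isn_trajectory")
}

#' Settle the network onto an attractor
#'
#' Integrates with no stimulus until convergence or `max_time` (default the
#' 12 s cap).  Convergence requires the max-norm rate change over a trailing
#' 5 ms window to fall below 1e-4 Hz and the flow-extrapolated fixed point
#' (`r + tau * dr/dt`) to lie within 0.1 Hz.  A timeout is a distinguishable
#' result (`is_timeout = TRUE`), not an error: persistent oscillation is
#' reported, not hidden.
#'
#' @inheritParams simulate
#' @param start Length-2N vector of starting rates (>= 0).
#' @param max_time Settling cap in ms (default 12000).
#' @param eps UP-signature threshold on excitatory rates (Hz).
#' @return An `attractor_state`: `rates`, logical `signature` (length N,
#'   `TRUE` = pair UP), `is_timeout`, `settle_time`.
#' @export
settle <- function(matrix, spec = attr(matrix, "spec"), start,
                   max_time = 12000, dt = 0.01, eps = 0.1) {
  if (any(start < 0)) stop("start rates must be >= 0", call. = FALSE)
  res <- .settle_rk4(unclass(matrix), theta_vector(spec), spec$tau,
                     as.numeric(start), dt, max_time,
                     5, 1e-4, 0.1)
  attractor_state(res$rates, n_pairs = spec$n_pairs,
                  is_timeout = !res$converged, settle_time = res$time,
                  eps = eps)
}
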