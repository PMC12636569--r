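#' Apply a single pulse then settle
#'
#' Convenience for the transition-mapping operations: deliver one
#' rectangular pulse from `start`, then settle with no stimulus.
#'
#' @inheritParams settle
#' @param stimulus A `stimulus_pulse` (onset is taken as 0).
#' @return An `attractor_state`.
#' @export
apply_pulse_and_settle <- function(matrix, spec = attr(matrix, "spec"),
                                   start, stimulus, dt = 0.01,
                                   max_time = 12000, eps = 0.1) {
  n_units <- nrow(matrix)
  w <- stimulus$weights
  if (is.null(w)) w <- rep(1, n_units)
  res <- .pulse_then_settle(unclass(matrix), theta_vector(spec), spec$tau,
                            as.numeric(start), stimulus$amplitude,
                            stimulus$duration, as.numeric(w), dt, max_time,
                            5, 1e-4, 0.1)
  attractor_state(res$rates, n_pairs = spec$n_pairs,
                  is_timeout = !res$converged, settle_time = res$time,
                  eps = eps)
}

#' Log-spaced stimulus sweep grid
#'
#' Default ranges follow the single-pair sweeps: amplitudes spanning
#' [theta_e / 2, 50 * theta_e] (100-fold) and durations [0.1, 100] ms
#' (1000-fold), both log-spaced.
#'
#' @param amplitudes Strictly positive, sorted amplitude grid; or
#' @param durations strictly positive, sorted duration grid (ms).
#' @param theta_e Excitatory threshold used for the default amplitude range.
#' @param n_amp,n_dur Grid resolution (default 20 x 20).
#' @return A list of class `sweep_grid` with `amplitudes` and `durations`.
#' @export
sweep_grid <- function(amplitudes = NULL, durations = NULL, theta_e = NULL,
                       n_amp = 20L, n_dur = 20L) {
  if (is.null(amplitudes)) {
    if (is.null(theta_e)) stop("give either amplitudes or theta_e",
                               call. = FALSE)
    amplitudes <- exp(seq(log(theta_e / 2), log(50 * theta_e),
                          length.out = n_amp))
  }
  if (is.null(durations))
    durations <- exp(seq(log(0.1), log(100), length.out = n_dur))
  if (any(amplitudes <= 0) || any(durations <= 0))
    stop("sweep grids must be strictly positive", call. = FALSE)
  if (is.unsorted(amplitudes) || is.unsorted(durations))
    stop("sweep grids must be sorted increasing", call. = FALSE)
  structure(list(amplitudes = amplitudes, durations = durations),
            class = "sweep_grid")
}

#' State-dependence sweep for a single pair
#'
#' For every (amplitude, duration) cell, the pulse is applied twice: once
#' from the DOWN state (origin) and once from the UP state (closed-form
#' fixed point), each followed by settling.  A cell is `state_dependent`
#' when the same stimulus drove DOWN to UP *and* UP to DOWN.
#'
#' @param pair A bistable `isp_params`.
#' @param grid A `sweep_grid`; default built from `pair$theta_e`.
#' @param tau Time constant (ms).
#' @param dt Integration step (ms).
#' @param max_time Settling cap (ms).
#' @return The grid with an `outcome` matrix (amplitude x duration) of
#'   factor levels `none`, `down_to_up_only`, `up_to_down_only`,
#'   `state_dependent`, or `NA` for timeout cells, plus a `timeout` logical
#'   matrix.
#' @export
state_dependence_sweep <- function(pair, grid = NULL, tau = 10, dt = 0.01,
                                   max_time = 12000) {
  bi <- is_bistable(pair, tau)
  if (!bi$bistable)
    stop("pair is not bistable: ", bi$diagnostic, call. = FALSE)
  if (is.null(grid)) grid <- sweep_grid(theta_e = pair$theta_e)
  spec <- network_spec(1L, pair, tau = tau)
  W <- build_weight_matrix(spec)
  fp <- fixed_point_up(pair)
  up_start <- c(fp$r_e, fp$r_i)
  na <- length(grid$amplitudes); nd <- length(grid$durations)
  outcome <- matrix(NA_character_, na, nd)
  timeout <- matrix(FALSE, na, nd)
  for (ai in seq_len(na)) for (di in seq_len(nd)) {
    stim <- stimulus_pulse(grid$amplitudes[ai], grid$durations[di])
    from_down <- apply_pulse_and_settle(W, spec, c(0, 0), stim, dt, max_time)
    from_up <- apply_pulse_and_settle(W, spec, up_start, stim, dt, max_time)
    if (from_down$is_timeout || from_up$is_timeout) {
      timeout[ai, di] <- TRUE
      next
    }
    d2u <- from_down$signature[1]
    u2d <- !from_up$signature[1]
    outcome[ai, di] <- if (d2u && u2d) "state_dependent"
      else if (d2u) "down_to_up_only"
      else if (u2d) "up_to_down_only"
      else "none"
  }
  grid$outcome <- outcome
  grid$timeout <- timeout
  class(grid) <- c("filled_sweep_grid", "sweep_grid")
  grid
}

#' Stimulus tolerance of a filled sweep
#'
#' A scale- and sampling-invariant robustness summary of the state-dependent
#' region of stimulus space.  The state-dependent cells define a bounding
#' sub-grid in (amplitude, duration); `f` is the state-dependent fraction of
#' the (non-timeout) cells in that box, and the fold ranges are
#' max/min over the state-dependent cells' amplitudes and durations.  The
#' region is treated as a circle on log-log axes of area
#' `f * fold_amp * fold_dur` and the tolerance is its diameter in
#' fold-variation units: `2 * sqrt(f * fold_amp * fold_dur / pi)`.  With no
#' state-dependent cell the tolerance is zero.
#'
#' @param grid A filled sweep grid from [state_dependence_sweep()].
#' @return A list of class `tolerance_result`: `f_state_dependent`,
#'   `fold_range_amp`, `fold_range_dur`, `tolerance`.
#' @export
tolerance <- function(grid) {
  if (is.null(grid$outcome)) stop("grid has not been filled", call. = FALSE)
  sd_cells <- which(grid$outcome == "state_dependent", arr.ind = TRUE)
  if (nrow(sd_cells) == 0L)
    return(structure(list(f_state_dependent = 0, fold_range_amp = 1,
                          fold_range_dur = 1, tolerance = 0),
                     class = "tolerance_result"))
  amps <- grid$amplitudes[sd_cells[, 1]]
  durs <- grid$durations[sd_cells[, 2]]
  fold_amp <- max(amps) / min(amps)
  fold_dur <- max(durs) / min(durs)
  box_a <- which(grid$amplitudes >= min(amps) & grid$amplitudes <= max(amps))
  box_d <- which(grid$durations >= min(durs) & grid$durations <= max(durs))
  in_box <- !grid$timeout[box_a, box_d, drop = FALSE]
  f <- nrow(sd_cells) / sum(in_box)
  structure(list(f_state_dependent = f, fold_range_amp = fold_amp,
                 fold_range_dur = fold_dur,
                 tolerance = 2 * sqrt(f * fold_amp * fold_dur / pi)),
            class = "tolerance_result")
}

#' Stimulus-evoked transition graph over attractor states
#'
#' From each known attractor, apply the stimulus once and settle; the result
#' is matched to the nearest known attractor (max-norm 0.1 Hz).  A settled
#' state matching no known attractor is registered as a new node and itself
#' processed, so the returned graph is closed: every node has out-degree
#' exactly one for the stimulus.
#'
#' @inheritParams apply_pulse_and_settle
#' @param attractors An `attractor_set` (or list of `attractor_state`).
#' @param stimulus_id Label stored on the edges.
#' @return A list of class `transition_graph`: `states` (node list),
#'   `edges` (data frame: `from`, `stimulus`, `to`, `timeout`).
#' @export
build_transition_graph <- function(matrix, spec = attr(matrix, "spec"),
                                   attractors, stimulus, stimulus_id = "S",
                                   dt = 0.01, max_time = 12000) {
  states <- if (inherits(attractors, "attractor_set")) attractors$states
            else attractors
  to <- integer(0); from <- integer(0); tmo <- logical(0)
  i <- 1L
  while (i <= length(states)) {
    res <- apply_pulse_and_settle(matrix, spec, states[[i]]$rates, stimulus,
                                  dt, max_time)
    j <- match_state(res, states)
    if (j == 0L) {
      states[[length(states) + 1L]] <- res
      j <- length(states)
    }
    from <- c(from, i); to <- c(to, j); tmo <- c(tmo, res$is_timeout)
    i <- i + 1L
  }
  structure(list(states = states,
                 edges = data.frame(from = from, stimulus = stimulus_id,
                                    to = to, timeout = tmo)),
            class = "transition_graph")
}

#' Longest itinerant walk of a functional transition graph
#'
#' Each node has exactly one outgoing edge per stimulus, so from any start
#' the walk is rho-shaped: a tail followed by a cycle.  Itinerancy counts
#' state-*changing* transitions: starting from each node, follow edges,
#' counting every transition whose target differs from its source, and stop
#' as soon as the walk reaches a previously visited state (the closing
#' transition of a multi-state cycle is counted; a self-loop is not, since
#' nothing moved).  L is the maximum over start nodes.  A homogeneous
#' network driven by a uniform stimulus attains at most
#' tail (2) + two-cycle (2) = 4.
#'
#' @param graph A `transition_graph`.
#' @param stimulus_id Which stimulus' edges to walk (default: the only one).
#' @return Integer L, the longest itinerant path length.
#' @export
longest_itinerant_path <- function(graph, stimulus_id = NULL) {
  ed <- graph$edges
  if (!is.null(stimulus_id)) ed <- ed[ed$stimulus == stimulus_id, ]
  nxt <- integer(max(c(ed$from, ed$to), 0L))
  nxt[ed$from] <- ed$to
  best <- 0L
  for (s in ed$from) {
    visited <- s
    cur <- s
    len <- 0L
    repeat {
      nx <- nxt[cur]
      if (nx %in% visited) {
        if (nx != cur) len <- len + 1L
        break
      }
      len <- len + 1L
      visited <- c(visited, nx)
      cur <- nx
    }
    best <- max(best, len)
  }
  best
}

#' Longest itinerant path over a stimulus grid
#'
#' For each (amplitude, duration) cell, builds the uniform-stimulus
#' transition graph over the network's attractors and records the longest
#' itinerant path L.  For homogeneous (cv = 0) matrices a permutation-
#' symmetry fast path is used: one representative state per stable k-class
#' is simulated, every pair in the same (UP or DOWN) role responds
#' identically, and the full functional graph follows (validated against
#' the generic path on small networks in the test-suite).
#'
#' @inheritParams build_transition_graph
#' @param grid A `sweep_grid` of amplitudes and durations.
#' @param attractors Optional pre-enumerated `attractor_set`; enumerated
#'   (homogeneous algorithm when applicable) if missing.
#' @param homogeneous Use the symmetry fast path; default auto-detect.
#' @return A list of class `itinerancy_map`: the grid plus an `L` matrix
#'   (amplitude x duration) and a `timeout` logical matrix.
#' @export
itinerancy_sweep <- function(matrix, spec = attr(matrix, "spec"), grid,
                             attractors = NULL, homogeneous = NULL,
                             dt = 0.01, max_time = 12000) {
  if (is.null(homogeneous))
    homogeneous <- is_homogeneous_matrix(matrix, spec)
  if (is.null(attractors)) {
    attractors <- if (homogeneous)
      enumerate_attractors_homogeneous(matrix, spec, dt = dt,
                                       max_time = max_time)
    else enumerate_attractors(matrix, spec, dt = dt, max_time = max_time)
  }
  na <- length(grid$amplitudes); nd <- length(grid$durations)
  L <- matrix(NA_integer_, na, nd)
  tmo <- matrix(FALSE, na, nd)
  for (ai in seq_len(na)) for (di in seq_len(nd)) {
    stim <- stimulus_pulse(grid$amplitudes[ai], grid$durations[di])
    if (homogeneous) {
      res <- homogeneous_cell_L(matrix, spec, attractors, stim, dt, max_time)
      L[ai, di] <- res$L
      tmo[ai, di] <- res$timeout
    } else {
      g <- build_transition_graph(matrix, spec, attractors, stim,
                                  dt = dt, max_time = max_time)
      tmo[ai, di] <- any(g$edges$timeout)
      L[ai, di] <- longest_itinerant_path(g)
    }
  }
  structure(list(amplitudes = grid$amplitudes, durations = grid$durations,
                 L = L, timeout = tmo),
            class = "itinerancy_map")
}

# Symmetry fast path for a homogeneous matrix under a uniform stimulus:
# from a state with UP set U, every UP pair responds identically and every
# DOWN pair responds identically, so the successor is one of
# {U, complement(U), all-UP, all-DOWN}.  Simulating one representative per
# stable k-class determines the (up_next, down_next) role map for that k;
# the longest walk is then computed over the induced four-state orbits.
homogeneous_cell_L <- function(matrix, spec, attractors, stim, dt, max_time) {
  n <- spec$n_pairs
  ks <- sort(unique(vapply(attractors$states, function(s) sum(s$signature),
                           integer(1))))
  # role map per k: what an UP pair and a DOWN pair each become
  up_next <- rep(NA, n + 1L)
  dn_next <- rep(NA, n + 1L)
  any_timeout <- FALSE
  for (k in ks) {
    rep_state <- attractors$states[[which(vapply(attractors$states,
      function(s) sum(s$signature), integer(1)) == k)[1]]]
    res <- apply_pulse_and_settle(matrix, spec, rep_state$rates, stim,
                                  dt, max_time)
    if (res$is_timeout) { any_timeout <- TRUE; next }
    src_up <- rep_state$signature
    if (k > 0L) up_next[k + 1L] <- res$signature[which(src_up)[1]]
    if (k < n) dn_next[k + 1L] <- res$signature[which(!src_up)[1]]
  }
  # walk the orbit {U, comp(U), all, none} per stable class
  step_of <- function(token, k0) {
    # token in c("U","C","A","N"); returns c(next_token, next_k)
    k <- switch(token, U = k0, C = n - k0, A = n, N = 0L)
    if (!(k %in% ks) || is.na(up_next[k + 1L]) && k > 0L ||
        is.na(dn_next[k + 1L]) && k < n) return(NULL)
    u <- if (k > 0L) up_next[k + 1L] else NA
    d <- if (k < n) dn_next[k + 1L] else NA
    if (k == 0L) return(if (d) c("A") else c("N"))
    if (k == n) return(if (u) c("A") else c("N"))
    if (u && !d) {
      if (token %in% c("U", "C")) token else token   # unchanged set
    } else if (!u && d) {
      switch(token, U = "C", C = "U", A = "N", N = "A")
    } else if (u && d) "A" else "N"
  }
  canon <- function(token, k0) {
    # map tokens with extreme k to their canonical identity so that e.g.
    # comp(U) with k0 = 0 equals all-UP
    k <- switch(token, U = k0, C = n - k0, A = n, N = 0L)
    if (k == 0L) return("N")
    if (k == n) return("A")
    token
  }
  best <- 0L
  for (k0 in ks) {
    cur <- canon("U", k0)
    visited <- cur
    len <- 0L
    repeat {
      nx <- step_of(cur, k0)
      if (is.null(nx)) { any_timeout <- TRUE; break }
      nx <- canon(nx, k0)
      if (nx %in% visited) {
        if (nx != cur) len <- len + 1L
        break
      }
      len <- len + 1L
      visited <- c(visited, nx)
      cur <- nx
    }
    best <- max(best, len)
  }
  list(L = best, timeout = any_timeout)
}
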