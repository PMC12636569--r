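# Shared fixtures and oracles.  dt = 0.05 ms is used throughout the suite
# (well inside the dt-robust regime for tau = 10 ms; the dt-convergence
# property test below guards this choice).

DT <- 0.05

fixtures <- make_fixtures(1)

spiral_pair <- fixtures$pair_spiral
node_pair <- fixtures$pair_node

pair_net <- function(pair, tau = 10) {
  sp <- network_spec(1L, pair, tau = tau)
  list(spec = sp, matrix = build_weight_matrix(sp))
}

# unrectified two-unit right-hand side, for independent oracles
pair_rhs <- function(r, pair, tau = 10, i_app = 0) {
  W <- matrix(c(pair$w_ee, pair$w_ie, pair$w_ei, pair$w_ii), 2, byrow = TRUE)
  (-r + W %*% r - c(pair$theta_e, pair$theta_i) + i_app) / tau
}

# forward-Euler oracle with rectified state (independent of the RK4 path)
euler_oracle <- function(W, theta, tau, r0, t_end, dt, amp = 0, onset = 0,
                         dur = 0, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(r0))
  r <- pmax(r0, 0)
  n <- round(t_end / dt)
  for (i in seq_len(n)) {
    t <- (i - 1) * dt
    I <- if (t >= onset && t < onset + dur) amp * weights else 0
    r <- r + dt * (-pmax(r, 0) + W %*% pmax(r, 0) - theta + I) / tau
    r <- pmax(r, 0)
  }
  drop(r)
}

# a small ready-made experiment config (N = 2, homogeneous weak coupling),
# with the suite's coarser dt for speed
build_config_fixture <- function() {
  raw <- list(
    seed = 1,
    network = list(n_pairs = 2, cross_frac = 0.1, cross_cv = 0,
                   pair_target = list(trace = -0.1, det = 0.01,
                                      theta_e = 5.34, theta_i = 82.43,
                                      r_e_up = 5, r_i_up = 10)),
    simulation = list(dt = DT, t_end = 200),
    task = list(cue_seed = 5, amplitude = 52, duration = 2))
  isnet:::build_config(raw)
}

# state equality re-coded: same UP/DOWN signature and rates within 0.1 Hz
states_equal_oracle <- function(a, b) {
  identical(a$signature, b$signature) && max(abs(a$rates - b$rates)) < 0.1
}

# brute-force longest-itinerant-walk oracle on a functional graph given as
# an integer successor vector (counts state-changing transitions, stopping
# at the first revisit; the closing transition counts unless a self-loop)
walk_oracle <- function(nxt) {
  best <- 0L
  for (s in seq_along(nxt)) {
    seen <- rep(FALSE, length(nxt))
    seen[s] <- TRUE
    cur <- s; len <- 0L
    repeat {
      nx <- nxt[cur]
      if (seen[nx]) { if (nx != cur) len <- len + 1L; break }
      len <- len + 1L
      seen[nx] <- TRUE
      cur <- nx
    }
    best <- max(best, len)
  }
  best
}
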