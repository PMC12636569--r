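#' Random cue weight-vector pair
#'
#' The two cues of the evidence-accumulation task are rectangular pulses
#' sharing one amplitude and duration, distinguished only by their per-unit
#' weight vectors.  Entries are drawn from a standard log-normal
#' distribution and each vector is rescaled to unit mean.
#'
#' @param n_units Number of rate units (2N), or a `network_spec`.
#' @param seed Integer RNG seed.
#' @return A list of class `cue_pair` with `omega_L`, `omega_R`, `seed`.
#' @export
make_cue_pair <- function(n_units, seed = 1L) {
  if (inherits(n_units, "network_spec")) n_units <- 2L * n_units$n_pairs
  with_seed(seed, {
    wl <- stats::rlnorm(n_units)
    wr <- stats::rlnorm(n_units)
    structure(list(omega_L = wl / mean(wl), omega_R = wr / mean(wr),
                   seed = as.integer(seed)),
              class = "cue_pair")
  })
}

#' Deterministic finite-state machine over the cue alphabet
#'
#' @param delta Integer |Q| x 2 matrix of successor state indices; columns
#'   are the symbols `L` and `R`.
#' @param q0 Initial state index (default 1).
#' @param states Optional list of `attractor_state` nodes backing the
#'   machine (may be `NULL` for abstract machines built in analyses).
#' @param outputs Optional character vector of per-state labels in
#'   `c("left", "right", "none")`.
#' @return An object of class `state_machine`.
#' @export
state_machine <- function(delta, q0 = 1L, states = NULL, outputs = NULL) {
  delta <- matrix(as.integer(delta), ncol = 2,
                  dimnames = list(NULL, c("L", "R")))
  m <- nrow(delta)
  if (any(delta < 1L) || any(delta > m))
    stop("transition table refers to states outside 1..|Q|", call. = FALSE)
  if (q0 < 1L || q0 > m) stop("q0 must index a state", call. = FALSE)
  structure(list(delta = delta, q0 = as.integer(q0), n_states = m,
                 alphabet = c("L", "R"), states = states, outputs = outputs),
            class = "state_machine")
}

#' @export
print.state_machine <- function(x, ...) {
  cat(sprintf("state_machine: %d states, q0 = %d, alphabet {L, R}\n",
              x$n_states, x$q0))
  if (!is.null(x$outputs))
    cat("  outputs:", paste(x$outputs, collapse = " "), "\n")
  invisible(x)
}

#' Extract the finite-state machine a network implements
#'
#' Breadth-first search over the two cue stimuli from the quiescent all-DOWN
#' state: for each discovered state, apply each cue pulse, settle
#' (equilibration is convergence-driven), and match the settled state to the
#' nearest known attractor (max-norm 0.1 Hz); unmatched states are added and
#' themselves processed.  Each discovered state is simulated exactly once
#' per symbol, so the total number of simulations is 2|Q|.
#'
#' @inheritParams apply_pulse_and_settle
#' @param cues A `cue_pair`.
#' @param amplitude,duration Shared pulse amplitude and duration (ms).
#' @return A `state_machine` (outputs unset) whose `states` hold the
#'   attractor nodes; state 1 is the quiescent initial state.
#' @export
extract_fsm <- function(matrix, spec = attr(matrix, "spec"), cues,
                        amplitude, duration, dt = 0.01, max_time = 12000) {
  q0 <- settle(matrix, spec, numeric(nrow(matrix)), max_time = max_time,
               dt = dt)
  if (q0$is_timeout)
    stop("quiescent state did not settle: check thresholds", call. = FALSE)
  states <- list(q0)
  delta <- matrix(NA_integer_, 1, 2)
  i <- 1L
  while (i <= length(states)) {
    for (sym in 1:2) {
      w <- if (sym == 1L) cues$omega_L else cues$omega_R
      stim <- stimulus_pulse(amplitude, duration, weights = w)
      res <- apply_pulse_and_settle(matrix, spec, states[[i]]$rates, stim,
                                    dt, max_time)
      if (res$is_timeout)
        stop(sprintf("settle timeout during FSM extraction at state %d, symbol %s",
                     i, c("L", "R")[sym]), call. = FALSE)
      j <- match_state(res, states)
      if (j == 0L) {
        states[[length(states) + 1L]] <- res
        delta <- rbind(delta, matrix(NA_integer_, 1, 2))
        j <- length(states)
      }
      delta[i, sym] <- j
    }
    i <- i + 1L
  }
  state_machine(delta, q0 = 1L, states = states)
}

# all binary sequences of a given length as a matrix of 1 (L) / 2 (R)
all_sequences <- function(length = 6L) {
  m <- as.matrix(expand.grid(rep(list(1:2), length))[, length:1, drop = FALSE])
  dimnames(m) <- list(apply(m, 1, function(r)
    paste(c("L", "R")[r], collapse = "")), NULL)
  m
}

#' Final machine state for every cue sequence
#'
#' A pure graph walk (no simulation): every one of the 2^length binary cue
#' sequences is traced through the transition table from `q0`.
#'
#' @param machine A `state_machine`.
#' @param length Sequence length (default 6).
#' @return A named integer vector: final state index per sequence, names
#'   like `"LLRLRR"`.
#' @export
evaluate_sequences <- function(machine, length = 6L) {
  seqs <- all_sequences(length)
  s <- rep(machine$q0, nrow(seqs))
  for (t in seq_len(ncol(seqs)))
    s <- machine$delta[cbind(s, seqs[, t])]
  stats::setNames(s, rownames(seqs))
}

# majority label of each sequence name: "left", "right" or "tie"
sequence_majority <- function(seq_names) {
  nl <- vapply(strsplit(seq_names, ""), function(ch) sum(ch == "L"),
               integer(1))
  len <- nchar(seq_names[1])
  ifelse(nl * 2 > len, "left", ifelse(nl * 2 < len, "right", "tie"))
}

#' Optimal output function and task reliability
#'
#' Sequences with more L than R cues form the set L, more R than L the set
#' R; equal-count sequences are excluded.  For each reachable final state
#' i with sequence set S_i, the optimal label is the majority class of S_i,
#' and reliability = sum_i max(|S_i n L|, |S_i n R|) / (|L| + |R|).  States
#' whose two overlaps tie (including both zero) are labelled `"none"`.
#' Reliability is 0.5 for a machine with no discrimination and 1.0 for
#' perfect separation.
#'
#' @param final_states Named vector from [evaluate_sequences()].
#' @return A list of class `task_outputs`: `reliability`, `outputs`
#'   (label per state index), `labels` (decision per sequence).
#' @export
optimal_output_and_reliability <- function(final_states) {
  maj <- sequence_majority(names(final_states))
  n_states <- max(final_states)
  outputs <- rep("none", n_states)
  correct <- 0L
  for (i in unique(final_states)) {
    in_i <- final_states == i
    nl <- sum(in_i & maj == "left")
    nr <- sum(in_i & maj == "right")
    correct <- correct + max(nl, nr)
    outputs[i] <- if (nl > nr) "left" else if (nr > nl) "right" else "none"
  }
  denom <- sum(maj != "tie")
  structure(list(reliability = correct / denom, outputs = outputs,
                 labels = outputs[final_states] |>
                   stats::setNames(names(final_states))),
            class = "task_outputs")
}

#' Psychometric curve
#'
#' P(left decision | k left cues) over all sequences with k left cues,
#' k = 0..length.
#'
#' @param final_states Named vector from [evaluate_sequences()].
#' @param outputs Label per state (from [optimal_output_and_reliability()]
#'   or user-set).
#' @return Numeric vector of length `length + 1`, named `k0..k6`.
#' @export
psychometric <- function(final_states, outputs) {
  labels <- outputs[final_states]
  nl <- vapply(strsplit(names(final_states), ""),
               function(ch) sum(ch == "L"), integer(1))
  len <- nchar(names(final_states)[1])
  p <- vapply(0:len, function(k) mean(labels[nl == k] == "left"), numeric(1))
  stats::setNames(p, paste0("k", 0:len))
}

#' Compare logistic and linear fits to a psychometric curve
#'
#' Weighted least squares (weights = number of sequences per k, i.e.
#' choose(length, k)) of a two-parameter logistic
#' `p = 1 / (1 + exp(-(b0 + b1 k)))` versus a straight line.  The model with
#' the smaller weighted residual sum of squares is reported as better; ties
#' go to the linear model (fewer effective degrees of freedom used by the
#' saturating curve).
#'
#' @param curve Psychometric curve from [psychometric()].
#' @return A list of class `psychometric_fit`: `logistic` (coefficients,
#'   wrss), `linear` (coefficients, wrss), `better`.
#' @export
psychometric_fit_comparison <- function(curve) {
  k <- seq_along(curve) - 1
  w <- choose(length(curve) - 1, k)
  lin <- stats::lm(curve ~ k, weights = w)
  wrss_lin <- sum(w * stats::resid(lin)^2)
  obj <- function(p) sum(w * (curve - stats::plogis(p[1] + p[2] * k))^2)
  # deterministic two-stage start: from the linear trend, then polish
  b1_0 <- 4 * stats::coef(lin)[2]
  b0_0 <- stats::qlogis(min(max(mean(curve), 1e-3), 1 - 1e-3)) -
    b1_0 * mean(k)
  op <- stats::optim(c(b0_0, b1_0), obj, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-14))
  op <- stats::optim(op$par, obj, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-14))
  structure(list(logistic = list(coef = stats::setNames(op$par, c("b0", "b1")),
                                 wrss = op$value),
                 linear = list(coef = stats::coef(lin), wrss = wrss_lin),
                 better = if (op$value < wrss_lin - 1e-12) "logistic"
                          else "linear"),
            class = "psychometric_fit")
}

#' Primacy and recency of the decisions
#'
#' Over sequences whose decision label is not `"none"`, the fraction whose
#' decision agrees with the first cue (primacy) and with the last cue
#' (recency); `"L"` agrees with `"left"`.
#'
#' @param labels Named decision labels per sequence (from
#'   [optimal_output_and_reliability()]).
#' @return Numeric vector `c(primacy = , recency = )`.
#' @export
primacy_recency <- function(labels) {
  decided <- labels != "none"
  if (!any(decided)) return(c(primacy = NA_real_, recency = NA_real_))
  nm <- names(labels)[decided]
  lab <- labels[decided]
  first <- ifelse(substr(nm, 1, 1) == "L", "left", "right")
  last <- ifelse(substr(nm, nchar(nm), nchar(nm)) == "L", "left", "right")
  c(primacy = mean(lab == first), recency = mean(lab == last))
}

#' Score the evidence-accumulation task over a stimulus grid
#'
#' For each (amplitude, duration) cell: extract the FSM, trace all
#' sequences, optimize the output function, and record reliability,
#' psychometric curve, primacy and recency.
#'
#' @inheritParams extract_fsm
#' @param grid A `sweep_grid`.
#' @param length Sequence length (default 6).
#' @return A data frame with one row per cell: `amplitude`, `duration`,
#'   `n_states`, `reliability`, `primacy`, `recency`; the list of machines
#'   is attached as attribute `"machines"`.
#' @export
task_sweep <- function(matrix, spec = attr(matrix, "spec"), cues, grid,
                       length = 6L, dt = 0.01, max_time = 12000) {
  rows <- list(); machines <- list()
  for (ai in seq_along(grid$amplitudes)) for (di in seq_along(grid$durations)) {
    amp <- grid$amplitudes[ai]; dur <- grid$durations[di]
    m <- extract_fsm(matrix, spec, cues, amp, dur, dt = dt,
                     max_time = max_time)
    fin <- evaluate_sequences(m, length)
    sc <- optimal_output_and_reliability(fin)
    pr <- primacy_recency(sc$labels)
    rows[[length(rows) + 1L]] <- data.frame(
      amplitude = amp, duration = dur, n_states = m$n_states,
      reliability = sc$reliability, primacy = pr["primacy"],
      recency = pr["recency"], row.names = NULL)
    machines[[length(machines) + 1L]] <- m
  }
  out <- do.call(rbind, rows)
  attr(out, "machines") <- machines
  out
}

#' Saturating difference-counter machine
#'
#' The canonical perfect solver of the majority task: states track
#' #L - #R, saturating at +/- `length`; reaching it requires
#' 2 * length + 1 = 13 states for length-6 sequences.  Used as a scoring
#' anchor (reliability exactly 1).
#'
#' @param length Sequence length (default 6).
#' @return A `state_machine`; state indices encode differences
#'   `-length..length` with q0 at difference 0.
#' @export
counter_machine <- function(length = 6L) {
  diffs <- -length:length
  idx <- function(d) match(max(min(d, length), -length), diffs)
  delta <- cbind(vapply(diffs, function(d) idx(d + 1L), integer(1)),
                 vapply(diffs, function(d) idx(d - 1L), integer(1)))
  state_machine(delta, q0 = idx(0L))
}

#' Minimum machine size for perfect task performance
#'
#' Exhaustive search over deterministic two-symbol machines: for m = 1, 2,
#' ... all m^(2m) transition tables with the initial state fixed at 1 (any
#' machine can be relabelled so q0 = 1 without changing its reliability),
#' scored with the optimal output function over all length-6 sequences.
#' Returns the smallest m attaining reliability 1, together with a witness.
#'
#' @param length Sequence length (default 6).
#' @param max_m Search bound.
#' @return A list of class `min_states_result`: `min_states`,
#'   `witness` (a perfect `state_machine`), `best_by_m` (best reliability
#'   found at each size searched).
#' @export
min_states_for_perfect <- function(length = 6L, max_m = 6L) {
  seqs <- all_sequences(length)
  maj <- sequence_majority(rownames(seqs))
  denom <- sum(maj != "tie")
  is_left <- maj == "left"; is_right <- maj == "right"
  best_by_m <- numeric(0)
  for (m in seq_len(max_m)) {
    n_tables <- m^(2 * m)
    best <- 0
    witness <- NULL
    for (ti in 0:(n_tables - 1)) {
      # decode table index into an m x 2 transition table, base m
      digits <- integer(2 * m)
      x <- ti
      for (d in seq_len(2 * m)) { digits[d] <- x %% m; x <- x %/% m }
      delta <- matrix(digits + 1L, nrow = m)
      s <- rep(1L, nrow(seqs))
      for (t in seq_len(ncol(seqs)))
        s <- delta[cbind(s, seqs[, t])]
      correct <- 0L
      for (i in unique(s)) {
        in_i <- s == i
        correct <- correct + max(sum(in_i & is_left), sum(in_i & is_right))
      }
      rel <- correct / denom
      if (rel > best) {
        best <- rel
        witness <- delta
        if (best >= 1) break
      }
    }
    best_by_m <- c(best_by_m, best)
    if (best >= 1) {
      wm <- state_machine(witness, q0 = 1L)
      fin <- evaluate_sequences(wm, length)
      wm$outputs <- optimal_output_and_reliability(fin)$outputs
      return(structure(list(min_states = m, witness = wm,
                            best_by_m = stats::setNames(best_by_m,
                                                        paste0("m", seq_len(m)))),
                       class = "min_states_result"))
    }
  }
  stop("no perfect machine found with up to ", max_m, " states", call. = FALSE)
}
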