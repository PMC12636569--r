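# Machine-theoretic scoring: anchors computed on machines built in code.

test_that("sequence bookkeeping and reliability anchors are exact", {
  fin1 <- evaluate_sequences(state_machine(matrix(c(1L, 1L), 1)), 6)
  expect_length(fin1, 64L)
  maj <- table(isnet:::sequence_majority(names(fin1)))
  expect_equal(unname(maj[c("left", "right", "tie")]), c(22L, 22L, 20L),
               ignore_attr = TRUE)

  # no discrimination -> 0.50
  expect_equal(optimal_output_and_reliability(fin1)$reliability, 0.5)

  # last-cue copier -> 8/11
  last_cue <- state_machine(matrix(c(1L, 1L, 2L, 2L), 2), q0 = 1L)
  rel_last <- optimal_output_and_reliability(evaluate_sequences(last_cue))
  expect_equal(rel_last$reliability, 8 / 11)

  # saturating difference counter -> 1.00, and its final state encodes #L - #R
  cm <- counter_machine(6)
  fin <- evaluate_sequences(cm, 6)
  nl <- vapply(strsplit(names(fin), ""), function(ch) sum(ch == "L"),
               integer(1))
  expect_true(all(fin == match(nl - (6 - nl), -6:6)))
  sc <- optimal_output_and_reliability(fin)
  expect_equal(sc$reliability, 1)

  # purity: re-walking gives identical results
  expect_identical(fin, evaluate_sequences(cm, 6))

  # reverse task (swap labels): reliability unchanged by symmetry
  swapped <- ifelse(sc$labels == "left", "right",
                    ifelse(sc$labels == "right", "left", "none"))
  maj2 <- isnet:::sequence_majority(names(fin))
  minority_ok <- sum((swapped == "left" & maj2 == "right") |
                       (swapped == "right" & maj2 == "left"))
  expect_equal(minority_ok / 44, 1)
})

test_that("psychometric curves and primacy/recency behave per construction", {
  cm <- counter_machine(6)
  fin <- evaluate_sequences(cm, 6)
  sc <- optimal_output_and_reliability(fin)
  p <- psychometric(fin, sc$outputs)
  expect_equal(unname(p[c("k0", "k1", "k2")]), c(0, 0, 0))
  expect_equal(unname(p[c("k4", "k5", "k6")]), c(1, 1, 1))

  # perfect machine: primacy = recency = 8/11 over decided sequences
  pr <- primacy_recency(sc$labels)
  expect_equal(unname(pr), c(8 / 11, 8 / 11))

  # last-cue machine: recency 1, P(left | k) = k/6 (enumeration identity)
  last_cue <- state_machine(matrix(c(1L, 1L, 2L, 2L), 2))
  finl <- evaluate_sequences(last_cue)
  outs <- c("left", "right")  # state 1 reached iff last cue was L
  pl <- psychometric(finl, outs)
  expect_equal(unname(pl), (0:6) / 6)
  labl <- setNames(outs[finl], names(finl))
  expect_equal(unname(primacy_recency(labl)["recency"]), 1)

  # first-cue machine: primacy 1
  first_cue <- state_machine(matrix(c(2L, 2L, 3L, 3L, 2L, 3L), 3,
                                    byrow = FALSE), q0 = 1L)
  finf <- evaluate_sequences(first_cue)
  labf <- setNames(c("none", "left", "right")[finf], names(finf))
  expect_equal(unname(primacy_recency(labf)["primacy"]), 1)
})

test_that("logistic vs linear comparison picks the right model", {
  # step curve: logistic wins
  step <- c(0, 0, 0, 0.5, 1, 1, 1)
  cmp <- psychometric_fit_comparison(step)
  expect_identical(cmp$better, "logistic")
  expect_lt(cmp$logistic$wrss, cmp$linear$wrss)

  # exactly linear curve: linear at least as good
  lin <- (0:6) / 6
  cmp2 <- psychometric_fit_comparison(lin)
  expect_identical(cmp2$better, "linear")

  # random curves: logistic wrss matches a fine-grid oracle
  set.seed(21)
  k <- 0:6; w <- choose(6, k)
  for (rep in 1:3) {
    curve <- plogis(-3 + rep * k) + rnorm(7, sd = 0.05)
    cmp3 <- psychometric_fit_comparison(curve)
    grid <- expand.grid(b0 = seq(-6, 2, by = 0.1), b1 = seq(0, 4, by = 0.05))
    wrss <- apply(grid, 1, function(p)
      sum(w * (curve - plogis(p[1] + p[2] * k))^2))
    expect_lte(cmp3$logistic$wrss, min(wrss) + 1e-6)
  }
})

test_that("cue pairs are unit-mean, seeded, and log-normal", {
  cues <- make_cue_pair(10, seed = 7)
  expect_equal(mean(cues$omega_L), 1, tolerance = 1e-12)
  expect_equal(mean(cues$omega_R), 1, tolerance = 1e-12)
  expect_true(all(cues$omega_L > 0))
  expect_identical(cues, make_cue_pair(10, seed = 7))
  expect_false(identical(cues$omega_L, make_cue_pair(10, seed = 8)$omega_L))

  # goodness of fit: log of entries is normal up to the rescaling shift
  big <- make_cue_pair(10000, seed = 11)
  z <- log(big$omega_L) + 0.5   # E[lnorm(0,1)] = exp(1/2)
  ks <- suppressWarnings(ks.test(z, "pnorm"))
  expect_gt(ks$p.value, 0.001)
})

test_that("extract_fsm matches exhaustive simulation on the 2-pair toy", {
  fx <- fixtures$net2_toy
  cues <- make_cue_pair(4, seed = 5)
  amp <- 52; dur <- 2
  m <- extract_fsm(fx$matrix, fx$spec, cues, amp, dur, dt = DT)

  # zero-amplitude pulse: a single state with two self-loops
  m0 <- extract_fsm(fx$matrix, fx$spec, cues, 1e-12, 1, dt = DT)
  expect_equal(m0$n_states, 1L)
  expect_equal(unname(m0$delta), matrix(1L, 1, 2), ignore_attr = TRUE)

  # exhaustive oracle: simulate both symbols from every enumerated attractor
  att <- enumerate_attractors(fx$matrix, fx$spec, dt = DT)
  for (i in seq_along(att$states)) {
    for (sym in 1:2) {
      w <- if (sym == 1) cues$omega_L else cues$omega_R
      res <- apply_pulse_and_settle(fx$matrix, fx$spec, att$states[[i]]$rates,
                                    stimulus_pulse(amp, dur, weights = w),
                                    dt = DT)
      # find the source and target in the machine's state list
      src <- which(vapply(m$states, states_equal_oracle, logical(1),
                          att$states[[i]]))
      tgt <- which(vapply(m$states, states_equal_oracle, logical(1), res))
      if (length(src) == 1) expect_equal(unname(m$delta[src, sym]), tgt)
    }
  }
})

test_that("FSM shortcut equals direct 6-pulse simulation on the N = 5 fixture", {
  fx <- fixtures$net5_hetero
  cues <- make_cue_pair(10, seed = 7)
  amp <- 52; dur <- 1
  m <- extract_fsm(fx$matrix, fx$spec, cues, amp, dur, dt = DT)
  fin <- evaluate_sequences(m, 6)

  # trace all 64 sequences by raw simulation along the prefix tree
  q0 <- settle(fx$matrix, fx$spec, numeric(10), dt = DT)
  walk <- function(rates, depth) {
    if (depth == 6) return(list(rates))
    out <- list()
    for (sym in 1:2) {
      w <- if (sym == 1) cues$omega_L else cues$omega_R
      res <- apply_pulse_and_settle(fx$matrix, fx$spec, rates,
                                    stimulus_pulse(amp, dur, weights = w),
                                    dt = DT)
      out <- c(out, walk(res$rates, depth + 1))
    }
    out
  }
  finals <- walk(q0$rates, 0)
  # sequence order from the recursion: symbol 1 (L) branch first at each
  # depth, i.e. names sorted with L < R — matches evaluate_sequences' grid
  seq_names <- names(fin)[order(names(fin))]
  fin_sorted <- fin[order(names(fin))]
  for (i in seq_along(finals)) {
    sim_state <- attractor_state(finals[[i]], n_pairs = 5)
    expect_identical(sim_state$signature,
                     m$states[[fin_sorted[i]]]$signature)
    expect_lt(max(abs(finals[[i]] - m$states[[fin_sorted[i]]]$rates)), 0.1)
  }
})

test_that("task_sweep composes scoring deterministically", {
  fx <- fixtures$net2_toy
  cues <- make_cue_pair(4, seed = 5)
  grid <- sweep_grid(amplitudes = c(1e-12, 52), durations = c(2))
  ts1 <- task_sweep(fx$matrix, fx$spec, cues, grid, dt = DT)
  ts2 <- task_sweep(fx$matrix, fx$spec, cues, grid, dt = DT)
  expect_equal(ts1$reliability, ts2$reliability)
  # zero-amplitude cell scores exactly at chance
  expect_equal(ts1$reliability[ts1$amplitude < 1e-6], 0.5)
  expect_true(all(ts1$reliability >= 0.5 & ts1$reliability <= 1))
})

test_that("two-state machines cannot beat the last-cue baseline", {
  seqs <- isnet:::all_sequences(6)
  maj <- isnet:::sequence_majority(rownames(seqs))
  best <- 0
  for (ti in 0:15) {
    digits <- integer(4); x <- ti
    for (d in 1:4) { digits[d] <- x %% 2; x <- x %/% 2 }
    delta <- matrix(digits + 1L, 2)
    s <- rep(1L, 64)
    for (t in 1:6) s <- delta[cbind(s, seqs[, t])]
    correct <- sum(vapply(unique(s), function(i)
      max(sum(s == i & maj == "left"), sum(s == i & maj == "right")),
      numeric(1)))
    best <- max(best, correct / 44)
  }
  expect_equal(best, 8 / 11)
})
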