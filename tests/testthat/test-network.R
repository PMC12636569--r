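test_that("weight matrix honours within-pair blocks, Dale's law and row stats", {
  # N = 1 reduces exactly to the pair block
  net1 <- pair_net(spiral_pair)
  expect_equal(unclass(net1$matrix), pair_weight_matrix(spiral_pair),
               ignore_attr = TRUE)

  # N = 5, cv = 0: all cross entries in a class equal mean/N
  sp5 <- network_spec(5L, spiral_pair,
                      cross_stats(0.2, 0.1, 0.4, 0.3, cv = 0), seed = 5L)
  W5 <- build_weight_matrix(sp5)
  cross_ee <- W5[1, c(3, 5, 7, 9)]    # E row, other E columns
  expect_equal(unname(cross_ee), rep(0.2 / 5, 4))
  cross_ie <- W5[1, c(4, 6, 8, 10)]
  expect_equal(unname(cross_ie), rep(-0.1 / 5, 4))

  # Dale's law: E columns >= 0, I columns <= 0
  sp9 <- network_spec(9L, spiral_pair,
                      fiducial_cross_stats(spiral_pair, 0.1, 0.5),
                      seed = 17L)
  W9 <- build_weight_matrix(sp9)
  eidx <- seq(1, 17, by = 2)
  expect_true(all(W9[, eidx] >= 0))
  expect_true(all(W9[, -eidx] <= 0))

  # per-row realized class means equal spec means to 1e-10 relative
  st <- fiducial_cross_stats(spiral_pair, 0.1, 0.5)
  for (row in c(1, 2, 9, 18)) {
    pr <- (row + 1) %/% 2
    tgt <- if (row %% 2 == 1) c(st$ee$mean, st$ie$mean)
           else c(st$ei$mean, st$ii$mean)
    ecols <- setdiff(eidx, 2 * pr - 1)
    icols <- setdiff(seq(2, 18, by = 2), 2 * pr)
    expect_equal(mean(abs(W9[row, ecols])), tgt[1] / 9, tolerance = 1e-10)
    expect_equal(mean(abs(W9[row, icols])), tgt[2] / 9, tolerance = 1e-10)
    expect_equal(sd(abs(W9[row, ecols])), st[[if (row %% 2 == 1) "ee" else "ei"]]$sd / 9,
                 tolerance = 1e-8)
  }

  # seed determinism
  expect_identical(unclass(build_weight_matrix(sp9)), unclass(W9))

  # infeasible stats signalled
  sp2 <- network_spec(2L, spiral_pair,
                      cross_stats(0.2, 0.1, 0.4, 0.3, cv = 0.5))
  expect_error(build_weight_matrix(sp2), "single cross partner")
})

test_that("heterogeneous gamma family keeps class means fixed across cv", {
  st <- fiducial_cross_stats(spiral_pair, 0.1, 0)
  sp <- network_spec(4L, spiral_pair, st, cross_family = "gamma", seed = 23L)
  fam <- build_heterogeneous_family(sp, cv_values = c(0, 0.5, 1),
                                    replicates = 2L)
  expect_length(fam, 6L)
  # cv = 0 replicates equal the homogeneous matrix
  Wh <- build_weight_matrix(network_spec(4L, spiral_pair,
                                         cross_stats(st$ee$mean, st$ie$mean,
                                                     st$ei$mean, st$ii$mean),
                                         seed = attr(fam[[1]], "spec")$seed))
  expect_equal(unclass(fam[[1]]), unclass(Wh), ignore_attr = TRUE)
  # per-row class means identical for every member (mean input constant)
  eidx <- seq(1, 7, by = 2)
  for (m in fam) {
    ecols <- setdiff(eidx, 1)
    expect_equal(mean(abs(m[1, ecols])), st$ee$mean / 4, tolerance = 1e-9)
  }
  # realized per-row cv equals the requested cv (exact stat matching)
  m1 <- fam[[5]]  # cv = 1, first replicate
  mags <- abs(m1[1, setdiff(eidx, 1)])
  expect_equal(sd(mags) / mean(mags), 1, tolerance = 1e-8)
})

test_that("simulate reproduces linear decay and holds fixed points", {
  # zero weights, zero thresholds: pure exponential decay
  p0 <- isp_params(0, 0, 0, 0, 0, 0)
  net <- pair_net(p0)
  r0 <- c(4, 7)
  tr <- simulate(net$matrix, net$spec, r0, t_end = 50, dt = DT)
  expect_equal(tr$final, r0 * exp(-50 / 10), tolerance = 1e-6)

  # bistable pair initialized at the UP fixed point stays there
  netb <- pair_net(spiral_pair)
  fp <- fixed_point_up(spiral_pair)
  trb <- simulate(netb$matrix, netb$spec, c(fp$r_e, fp$r_i), t_end = 200,
                  dt = DT)
  expect_lt(max(abs(trb$final - c(fp$r_e, fp$r_i))), 1e-6)

  # trajectories are non-negative everywhere
  trs <- simulate(netb$matrix, netb$spec, c(0, 0),
                  stimuli = stimulus_pulse(52.15, 1, onset = 5),
                  t_end = 300, dt = DT)
  expect_true(all(trs$rates >= 0))
})

test_that("RK4 agrees with a fine-step forward-Euler oracle", {
  netb <- pair_net(spiral_pair)
  theta <- c(spiral_pair$theta_e, spiral_pair$theta_i)
  tr <- simulate(netb$matrix, netb$spec, c(0, 0),
                 stimuli = stimulus_pulse(52.15, 1, onset = 5),
                 t_end = 100, dt = 0.01)
  eu <- euler_oracle(unclass(netb$matrix), theta, 10, c(0, 0),
                     t_end = 100, dt = 0.01 / 100, amp = 52.15, onset = 5,
                     dur = 1)
  expect_lt(max(abs(tr$final - eu)), 1e-3)
})

test_that("settled attractors are dt-robust on the fixture networks", {
  for (fx in list(fixtures$net2_toy, fixtures$net5_hetero)) {
    n <- fx$spec$n_pairs
    start <- pmax(rep(c(5, 10), n) + 0.5, 0)
    a <- settle(fx$matrix, fx$spec, start, dt = DT)
    b <- settle(fx$matrix, fx$spec, start, dt = DT / 2)
    expect_identical(a$signature, b$signature)
    expect_lt(max(abs(a$rates - b$rates)), 0.1)
  }
})

test_that("UP state shows the paradoxical response to inhibitory drive", {
  netb <- pair_net(spiral_pair)
  fp <- fixed_point_up(spiral_pair)
  # small sustained current to the inhibitory unit only
  tr <- simulate(netb$matrix, netb$spec, c(fp$r_e, fp$r_i),
                 stimuli = stimulus_pulse(0.5, duration = 600, onset = 0,
                                          weights = c(0, 2)),
                 t_end = 500, dt = DT)
  expect_lt(tr$final[1], fp$r_e)
  expect_lt(tr$final[2], fp$r_i)
  expect_true(all(tr$final > 0))
})

test_that("settle reports timeouts distinguishably near the stability boundary", {
  marginal <- solve_pair_weights(-1e-4, 0.01, 5.34, 82.43, 5, 10)
  net <- pair_net(marginal)
  fp <- fixed_point_up(marginal)
  # a small orbit around the nearly undamped spiral does not decay within
  # the cap: reported as timeout, not as convergence and not as an error
  st <- settle(net$matrix, net$spec, c(fp$r_e + 0.3, fp$r_i + 0.3),
               max_time = 300, dt = DT)
  expect_true(st$is_timeout)
})

test_that("divergence aborts with a step diagnostic", {
  runaway <- isp_params(5, 0, 0, 0, theta_e = -1, theta_i = -1)
  net <- pair_net(runaway)
  expect_error(simulate(net$matrix, net$spec, c(1, 1), t_end = 5000, dt = 1),
               "diverged")
})
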