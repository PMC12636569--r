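# Experiment configuration and deterministic fixtures.  Configs are JSON;
# every stochastic component's seed is derived from the global seed plus a
# stable component label, so no hidden RNG state crosses module boundaries.

config_defaults <- list(tau = 10, dt = 0.01, settle_cap = 12000,
                        cross_family = "lognormal", scale_with_n = TRUE)

require_key <- function(x, key, where) {
  if (is.null(x[[key]]))
    stop("config schema violation: missing '", where, ".", key, "'",
         call. = FALSE)
  x[[key]]
}

#' Load and validate an experiment configuration
#'
#' Reads a JSON config, applies defaults (tau = 10 ms, dt = 0.01 ms, settle
#' cap 12000 ms) and validates the schema; violations name the offending
#' key.  The network's pair may be given either as explicit weights
#' (`network.pair`) or as an inverse-design target
#' (`network.pair_target` with `trace`, `det`, `theta_e`, `theta_i`,
#' `r_e_up`, `r_i_up`).
#'
#' @param path Path to a JSON config file.
#' @return A list of class `experiment_config` with a fully built
#'   `network_spec` under `$network_spec`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  build_config(raw)
}

build_config <- function(raw) {
  net <- raw[["network"]]
  if (is.null(net)) stop("config schema violation: missing 'network'",
                         call. = FALSE)
  n_pairs <- require_key(net, "n_pairs", "network")
  tau <- net[["tau"]] %||% config_defaults$tau
  pair <- if (!is.null(net[["pair"]])) {
    p <- net[["pair"]]
    for (k in c("w_ee", "w_ie", "w_ei", "w_ii", "theta_e", "theta_i"))
      require_key(p, k, "network.pair")
    isp_params(p$w_ee, p$w_ie, p$w_ei, p$w_ii, p$theta_e, p$theta_i)
  } else if (!is.null(net[["pair_target"]])) {
    tg <- net[["pair_target"]]
    for (k in c("trace", "det", "theta_e", "theta_i", "r_e_up", "r_i_up"))
      require_key(tg, k, "network.pair_target")
    solve_pair_weights(tg$trace, tg$det, tg$theta_e, tg$theta_i,
                       tg$r_e_up, tg$r_i_up, tau = tau)
  } else {
    stop("config schema violation: need 'network.pair' or 'network.pair_target'",
         call. = FALSE)
  }
  cs <- if (!is.null(net[["cross"]])) {
    cr <- net[["cross"]]
    cross_stats(cr$mean_ee %||% 0, cr$mean_ie %||% 0, cr$mean_ei %||% 0,
                cr$mean_ii %||% 0, cv = cr$cv %||% 0)
  } else if (!is.null(net[["cross_frac"]])) {
    fiducial_cross_stats(pair, frac = net[["cross_frac"]], cv = net[["cross_cv"]] %||% 0.5)
  } else cross_stats(0, 0, 0, 0)
  seed <- as.integer(raw[["seed"]] %||% 1L)
  spec <- network_spec(
    n_pairs, pair, cs,
    cross_family = net[["cross_family"]] %||% config_defaults$cross_family,
    scale_with_n = net[["scale_with_n"]] %||% config_defaults$scale_with_n,
    tau = tau,
    seed = as.integer(net[["seed"]] %||% derive_seed(seed, "network")))
  sim <- raw[["simulation"]] %||% list()
  structure(list(
    seed = seed,
    network = net,
    network_spec = spec,
    simulation = list(dt = sim$dt %||% config_defaults$dt,
                      t_end = sim$t_end %||% 1000,
                      settle_cap = sim$settle_cap %||% config_defaults$settle_cap),
    sweep = raw[["sweep"]],
    task = raw[["task"]],
    raw = raw),
    class = "experiment_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a configuration back to JSON
#'
#' Dumps the raw (defaults-filled) config; `load_config(dump_config(x))`
#' round-trips.
#'
#' @param config An `experiment_config`.
#' @param path Output path.
#' @export
dump_config <- function(config, path) {
  raw <- config$raw
  raw[["seed"]] <- config$seed
  raw[["simulation"]] <- config$simulation
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Deterministic fixture networks
#'
#' Seeded reference objects used throughout the test-suite and examples:
#' \describe{
#'   \item{pair_spiral}{bistable pair solved at (trace, det) =
#'     (-0.1, 0.01) 1/ms: a stable spiral (trace^2 < 4 det), thresholds
#'     (5.34, 82.43), UP rates (5, 10) Hz.}
#'   \item{pair_node}{bistable pair solved at (-0.4, 0.01): a stable node.}
#'   \item{net2_toy}{N = 2, homogeneous weak cross-connections (with a
#'     single cross partner per class, cv > 0 is infeasible).}
#'   \item{net5_hetero}{N = 5, gamma cross-connections with cv = 0.75.}
#'   \item{net9_homog}{N = 9, homogeneous (cv = 0) weak cross-connections.}
#' }
#' Regenerating a fixture from the same seed reproduces it bit-exactly.
#'
#' @param seed Global fixture seed.
#' @return A named list of class `fixture_set`; network entries hold
#'   `$spec` and the built `$matrix`.
#' @export
make_fixtures <- function(seed = 1L) {
  pair_spiral <- solve_pair_weights(-0.1, 0.01, 5.34, 82.43, 5, 10, tau = 10)
  pair_node <- solve_pair_weights(-0.4, 0.01, 5.34, 82.43, 5, 10, tau = 10)
  net <- function(n, pair, cv, family, label, frac = 0.1) {
    sp <- network_spec(n, pair, fiducial_cross_stats(pair, frac = frac,
                                                     cv = cv),
                       cross_family = family, scale_with_n = TRUE, tau = 10,
                       seed = derive_seed(seed, label))
    list(spec = sp, matrix = build_weight_matrix(sp))
  }
  structure(list(
    pair_spiral = pair_spiral,
    pair_node = pair_node,
    net2_toy = net(2L, pair_spiral, 0, "lognormal", "net2_toy"),
    net5_hetero = net(5L, pair_spiral, 0.75, "gamma", "net5_hetero"),
    net9_homog = net(9L, pair_spiral, 0, "lognormal", "net9_homog")),
    class = "fixture_set")
}

#' Run a configured experiment
#'
#' Dispatches to the analysis pipelines and writes result files (CSV/JSON)
#' with provenance headers.  Supported tasks: `"count-states"` (attractor
#' enumeration, homogeneous algorithm when the config's cv is 0),
#' `"simulate"` (one trajectory), `"itinerancy"` (longest-path sweep) and
#' `"fsm"` (machine extraction and task scores).
#'
#' @param config An `experiment_config` (or path to one).
#' @param task Which pipeline to run.
#' @param out_dir Output directory (created if needed).
#' @param homogeneous For `"count-states"`: use the O(N) symmetric
#'   enumeration (requires a cv = 0 network).
#' @return Invisibly, a named list of the files written and the primary
#'   result object.
#' @export
run_experiment <- function(config, task = c("count-states", "simulate",
                                            "itinerancy", "fsm"),
                           out_dir = ".", homogeneous = FALSE) {
  if (is.character(config)) config <- load_config(config)
  task <- match.arg(task)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- config$network_spec
  W <- build_weight_matrix(spec)
  dt <- config$simulation$dt
  cap <- config$simulation$settle_cap
  files <- character(0)
  result <- switch(task,
    "count-states" = {
      att <- if (homogeneous)
        enumerate_attractors_homogeneous(W, spec, dt = dt, max_time = cap)
      else enumerate_attractors(W, spec, dt = dt, max_time = cap)
      f <- file.path(out_dir, "states.csv")
      write_states_csv(att, f, seed = config$seed, dt = dt)
      files <- c(files, f)
      att
    },
    "simulate" = {
      stim <- if (!is.null(config$raw[["stimulus"]])) {
        s <- config$raw[["stimulus"]]
        list(stimulus_pulse(require_key(s, "amplitude", "stimulus"),
                            require_key(s, "duration", "stimulus"),
                            s$onset %||% 0))
      } else list()
      traj <- simulate(W, spec, initial = numeric(nrow(W)), stimuli = stim,
                       t_end = config$simulation$t_end, dt = dt)
      f <- file.path(out_dir, "trajectory.csv")
      write_trajectory(traj, f, seed = config$seed)
      files <- c(files, f)
      traj
    },
    "itinerancy" = {
      sw <- config$sweep %||% list()
      grid <- sweep_grid(theta_e = spec$pair$theta_e,
                         n_amp = sw$n_amp %||% 20L, n_dur = sw$n_dur %||% 20L)
      imap <- itinerancy_sweep(W, spec, grid, dt = dt, max_time = cap)
      f <- file.path(out_dir, "itinerancy.csv")
      df <- expand.grid(amplitude = imap$amplitudes,
                        duration = imap$durations)
      df$L <- as.vector(imap$L)
      df$timeout <- as.vector(imap$timeout)
      con <- file(f, "w")
      writeLines(result_header(seed = config$seed, dt = dt), con)
      utils::write.csv(df, con, row.names = FALSE)
      close(con)
      files <- c(files, f)
      imap
    },
    "fsm" = {
      tk <- config$task %||% list()
      cues <- make_cue_pair(2L * spec$n_pairs,
                            seed = tk$cue_seed %||%
                              derive_seed(config$seed, "cues"))
      m <- extract_fsm(W, spec, cues,
                       amplitude = require_key(tk, "amplitude", "task"),
                       duration = require_key(tk, "duration", "task"),
                       dt = dt, max_time = cap)
      fin <- evaluate_sequences(m, tk$length %||% 6L)
      sc <- optimal_output_and_reliability(fin)
      m$outputs <- sc$outputs
      f1 <- file.path(out_dir, "machine.json")
      write_machine_json(m, f1)
      f2 <- file.path(out_dir, "machine.dot")
      write_graph_dot(m, f2)
      f3 <- file.path(out_dir, "task_scores.csv")
      pr <- primacy_recency(sc$labels)
      con <- file(f3, "w")
      writeLines(result_header(seed = config$seed, dt = dt), con)
      utils::write.csv(data.frame(n_states = m$n_states,
                                  reliability = sc$reliability,
                                  primacy = pr["primacy"],
                                  recency = pr["recency"],
                                  row.names = NULL),
                       con, row.names = FALSE)
      close(con)
      files <- c(files, f1, f2, f3)
      list(machine = m, score = sc)
    })
  invisible(list(files = files, result = result))
}
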