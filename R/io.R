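# File I/O: weight matrices and trajectories as commented CSV, state
# machines as JSON, transition graphs as DOT.  Result tables carry a header
# comment with config hash, seed, dt and package version so any file can be
# regenerated from its own metadata.

result_header <- function(seed = NA, dt = NA, extra = character()) {
  c(sprintf("# isnet %s", as.character(utils::packageVersion("isnet"))),
    sprintf("# seed=%s dt=%s", seed, dt),
    if (length(extra)) paste0("# ", extra))
}

#' Write a weight matrix to CSV
#'
#' Dense CSV with unit labels (`E0, I0, E1, ...`) as header row and row
#' names; lines starting with `#` carry provenance metadata.
#'
#' @param matrix An `isn_weight_matrix`.
#' @param path Output file.
#' @export
write_weight_matrix <- function(matrix, path) {
  spec <- attr(matrix, "spec")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(result_header(seed = if (!is.null(spec)) spec$seed else NA), con)
  utils::write.csv(as.data.frame(unclass(matrix)), con, row.names = TRUE)
  invisible(path)
}

#' Read a weight matrix written by [write_weight_matrix()]
#'
#' @param path CSV file.
#' @return A numeric matrix with unit labels (no spec attached).
#' @export
read_weight_matrix <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", row.names = 1,
                        check.names = FALSE)
  as.matrix(df)
}

#' Write a trajectory to CSV
#'
#' One `time_ms` column plus one column per unit.
#'
#' @param traj An `isn_trajectory`.
#' @param path Output file.
#' @param seed,dt Provenance recorded in the header comment.
#' @export
write_trajectory <- function(traj, path, seed = NA, dt = traj$dt) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(result_header(seed = seed, dt = dt), con)
  utils::write.csv(data.frame(time_ms = traj$times, traj$rates,
                              check.names = FALSE),
                   con, row.names = FALSE)
  invisible(path)
}

#' Write an attractor set to CSV
#'
#' One row per state: UP/DOWN signature string, multiplicity (1 unless the
#' homogeneous enumeration credited permutations) and the settled rates.
#'
#' @param attractors An `attractor_set`.
#' @param path Output file.
#' @param seed,dt Provenance for the header comment.
#' @export
write_states_csv <- function(attractors, path, seed = NA, dt = NA) {
  states <- attractors$states
  rates <- do.call(rbind, lapply(states, `[[`, "rates"))
  df <- data.frame(
    signature = vapply(states, signature_string, character(1)),
    multiplicity = vapply(states, function(s) {
      m <- attr(s, "multiplicity"); if (is.null(m)) 1 else m
    }, numeric(1)))
  colnames(rates) <- unit_labels(ncol(rates) %/% 2L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(result_header(seed = seed, dt = dt,
                           extra = sprintf("states=%d timeouts=%d",
                                           attractors$count,
                                           attractors$n_timeouts)), con)
  utils::write.csv(cbind(df, rates), con, row.names = FALSE)
  invisible(path)
}

#' Serialize a state machine to JSON
#'
#' States (signatures and rates when backed by a network), initial state,
#' alphabet, transition table and output labels.
#'
#' @param machine A `state_machine`.
#' @param path Output file.
#' @export
write_machine_json <- function(machine, path) {
  obj <- list(
    n_states = machine$n_states,
    q0 = machine$q0,
    alphabet = machine$alphabet,
    delta = machine$delta,
    outputs = if (is.null(machine$outputs)) NULL else machine$outputs,
    states = if (is.null(machine$states)) NULL else
      lapply(machine$states, function(s)
        list(signature = signature_string(s), rates = s$rates)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a state machine written by [write_machine_json()]
#'
#' @param path JSON file.
#' @return A `state_machine` (attractor nodes restored as plain rate
#'   vectors).
#' @export
read_machine_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  states <- NULL
  if (!is.null(obj$states)) {
    if (is.data.frame(obj$states)) {
      states <- lapply(seq_len(nrow(obj$states)), function(i)
        attractor_state(unlist(obj$states$rates[i])))
    } else {
      states <- lapply(obj$states, function(s)
        attractor_state(as.numeric(s$rates)))
    }
  }
  state_machine(matrix(obj$delta, ncol = 2), q0 = obj$q0, states = states,
                outputs = obj$outputs)
}

#' Export a transition graph or state machine as DOT
#'
#' Nodes are labelled by UP/DOWN signature; edges by stimulus symbol.
#'
#' @param x A `transition_graph` or `state_machine`.
#' @param path Output file.
#' @export
write_graph_dot <- function(x, path) {
  lines <- c("digraph isnet {")
  if (inherits(x, "transition_graph")) {
    for (i in seq_along(x$states))
      lines <- c(lines, sprintf('  n%d [label="%s"];', i,
                                signature_string(x$states[[i]])))
    for (e in seq_len(nrow(x$edges)))
      lines <- c(lines, sprintf('  n%d -> n%d [label="%s"];',
                                x$edges$from[e], x$edges$to[e],
                                x$edges$stimulus[e]))
  } else if (inherits(x, "state_machine")) {
    for (i in seq_len(x$n_states)) {
      lab <- if (!is.null(x$states)) signature_string(x$states[[i]])
             else as.character(i)
      out <- if (!is.null(x$outputs)) paste0("\\n", x$outputs[i]) else ""
      lines <- c(lines, sprintf('  n%d [label="%s%s"];', i, lab, out))
    }
    for (i in seq_len(x$n_states)) for (s in 1:2)
      lines <- c(lines, sprintf('  n%d -> n%d [label="%s"];',
                                i, x$delta[i, s], c("L", "R")[s]))
  } else stop("cannot export this object as DOT", call. = FALSE)
  writeLines(c(lines, "}"), path)
  invisible(path)
}
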