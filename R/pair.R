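#' Within-pair parameters of an inhibition-stabilized pair
#'
#' An inhibition-stabilized pair (ISP) is one excitatory and one inhibitory
#' threshold-linear rate unit with strong mutual coupling.  The pair is
#' described by four signed weights and two activation thresholds.  Dale's
#' law fixes the signs: the excitatory unit's outgoing weights (`w_ee`,
#' `w_ei`) are non-negative and the inhibitory unit's (`w_ie`, `w_ii`) are
#' non-positive.
#'
#' @param w_ee E-to-E weight (dimensionless gain), >= 0.
#' @param w_ie I-to-E weight, <= 0.
#' @param w_ei E-to-I weight, >= 0.
#' @param w_ii I-to-I weight, <= 0.
#' @param theta_e Excitatory activation threshold (input-current units).
#' @param theta_i Inhibitory activation threshold.
#' @return An object of class `isp_params`.
#' @export
isp_params <- function(w_ee, w_ie, w_ei, w_ii, theta_e, theta_i) {
  for (nm in c("w_ee", "w_ie", "w_ei", "w_ii", "theta_e", "theta_i")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a finite numeric scalar", call. = FALSE)
  }
  if (w_ee < 0 || w_ei < 0)
    stop("Dale's law violated: excitatory outgoing weights must be >= 0",
         call. = FALSE)
  if (w_ie > 0 || w_ii > 0)
    stop("Dale's law violated: inhibitory outgoing weights must be <= 0",
         call. = FALSE)
  structure(list(w_ee = w_ee, w_ie = w_ie, w_ei = w_ei, w_ii = w_ii,
                 theta_e = theta_e, theta_i = theta_i),
            class = "isp_params")
}

#' @export
print.isp_params <- function(x, ...) {
  cat("Inhibition-stabilized pair\n")
  cat(sprintf("  weights:    w_ee = %.6g  w_ie = %.6g\n", x$w_ee, x$w_ie))
  cat(sprintf("              w_ei = %.6g  w_ii = %.6g\n", x$w_ei, x$w_ii))
  cat(sprintf("  thresholds: theta_e = %.6g  theta_i = %.6g\n",
              x$theta_e, x$theta_i))
  invisible(x)
}

#' Within-pair 2x2 weight matrix
#'
#' Entry (i, j) is the weight of the connection from unit j onto unit i,
#' matching the W.r convention of the network rate equation.
#'
#' @param params An `isp_params` object.
#' @return A 2x2 numeric matrix, rows/columns ordered (E, I).
#' @export
pair_weight_matrix <- function(params) {
  matrix(c(params$w_ee, params$w_ie,
           params$w_ei, params$w_ii),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("E0", "I0"), c("E0", "I0")))
}

#' Closed-form non-zero (UP) fixed point of a single pair
#'
#' Solves the unrectified linear steady state of the two-unit system under a
#' constant applied current `i_app` delivered equally to both units.  The
#' candidate may have negative components; in the rectified system it exists
#' as an attractor only when both rates are positive, which the caller
#' inspects.
#'
#' @param params An `isp_params` object.
#' @param i_app Constant applied current (0 for the autonomous system).
#' @return A list of class `isp_fixed_point` with `r_e`, `r_i` (Hz) and
#'   `kind = "up"`.
#' @export
fixed_point_up <- function(params, i_app = 0) {
  p <- params
  denom <- (p$w_ee - 1) * (p$w_ii - 1) - p$w_ei * p$w_ie
  if (abs(denom) < 1e-12)
    stop("singular fixed-point denominator: (w_ii - 1)(w_ee - 1) = w_ei * w_ie",
         call. = FALSE)
  be <- p$theta_e - i_app
  bi <- p$theta_i - i_app
  r_e <- (be * (p$w_ii - 1) - p$w_ie * bi) / denom
  r_i <- ((p$w_ee - 1) * bi - p$w_ei * be) / denom
  structure(list(r_e = r_e, r_i = r_i, kind = "up"),
            class = "isp_fixed_point")
}

#' Trace, determinant and stability class of the pair Jacobian
#'
#' The Jacobian of the two-unit system at the non-zero fixed point is
#' `(1/tau) * [[w_ee - 1, w_ie], [w_ei, w_ii - 1]]`.  The fixed point is
#' stable iff trace < 0 and determinant > 0; within the stable region it is
#' a spiral iff trace^2 < 4 * determinant.  Points within `tol` of the
#' node/spiral boundary (or of the stability boundaries) are labelled
#' `"boundary"` rather than silently binned.
#'
#' @param params An `isp_params` object.
#' @param tau Rate time constant (ms).
#' @param tol Numerical tolerance for boundary classification.
#' @return A list of class `jacobian_summary` with `trace` (1/ms),
#'   `determinant` (1/ms^2) and `classification`, one of `"stable_node"`,
#'   `"stable_spiral"`, `"unstable"`, `"saddle"`, `"boundary"`.
#' @export
jacobian_summary <- function(params, tau = 10, tol = 1e-9) {
  tr <- (params$w_ee + params$w_ii - 2) / tau
  det <- ((params$w_ee - 1) * (params$w_ii - 1) -
            params$w_ei * params$w_ie) / tau^2
  structure(list(trace = tr, determinant = det,
                 classification = classify_fixed_point(tr, det, tol)),
            class = "jacobian_summary")
}

#' @export
print.jacobian_summary <- function(x, ...) {
  cat(sprintf("jacobian_summary: trace = %.6g, determinant = %.6g  [%s]\n",
              x$trace, x$determinant, x$classification))
  invisible(x)
}

classify_fixed_point <- function(tr, det, tol = 1e-9) {
  if (det < -tol) return("saddle")
  if (abs(det) <= tol || abs(tr) <= tol) return("boundary")
  if (tr > 0) return("unstable")
  disc <- tr^2 - 4 * det
  if (abs(disc) <= tol) return("boundary")
  if (disc > 0) "stable_node" else "stable_spiral"
}

#' Test a single pair for bistability
#'
#' A pair is bistable (coexisting quiescent DOWN state and inhibition-
#' stabilized UP state) when (1) `theta_i > theta_e > 0`, so the origin of
#' the rectified system is an attractor, (2) the inhibitory nullcline has a
#' higher gain (steeper slope in the (r_E, r_I) plane) than the excitatory
#' nullcline, and (3) the closed-form UP fixed point has positive rates and
#' a stable Jacobian.
#'
#' @param params An `isp_params` object.
#' @param tau Rate time constant (ms).
#' @return A list of class `isp_bistability` with logical `bistable` and a
#'   character `diagnostic` naming the first failed condition (`"ok"` when
#'   bistable).
#' @export
is_bistable <- function(params, tau = 10) {
  p <- params
  fail <- function(msg) structure(list(bistable = FALSE, diagnostic = msg),
                                  class = "isp_bistability")
  if (!(p$theta_e > 0 && p$theta_i > 0))
    return(fail("origin not stable: thresholds must satisfy theta_i > theta_e > 0"))
  if (!(p$theta_i > p$theta_e))
    return(fail("threshold ordering violated: theta_i must exceed theta_e"))
  # nullcline gains in the (r_E, r_I) plane; w_ie = 0 means inhibition never
  # feeds back onto E, so no inhibitory stabilization is possible
  if (p$w_ie == 0 || p$w_ii >= 1)
    return(fail("inhibitory gain not greater than excitatory gain"))
  slope_e <- (1 - p$w_ee) / p$w_ie
  slope_i <- p$w_ei / (1 - p$w_ii)
  if (!(slope_i > slope_e))
    return(fail("inhibitory gain not greater than excitatory gain"))
  fp <- tryCatch(fixed_point_up(p), error = function(e) NULL)
  if (is.null(fp) || !(fp$r_e > 0 && fp$r_i > 0))
    return(fail("no positive UP fixed point"))
  js <- jacobian_summary(p, tau)
  if (!js$classification %in% c("stable_node", "stable_spiral"))
    return(fail(paste0("UP fixed point not stable (", js$classification, ")")))
  structure(list(bistable = TRUE, diagnostic = "ok"),
            class = "isp_bistability")
}

#' Solve within-pair weights from a target Jacobian and UP state
#'
#' Inverse design of a bistable pair: given target trace and determinant of
#' the UP-state Jacobian, the two thresholds, and the desired UP rates, find
#' the four within-pair weights.  Three of the four constraints are linear
#' in the weights; substituting them reduces the problem to a quadratic in
#' `w_ee`, which is solved in closed form (the "root solver" therefore
#' terminates deterministically).  Among real roots, the Dale-compliant one
#' is returned; when both comply, the one with larger `w_ee` (stronger
#' recurrent excitation, the canonical inhibition-stabilized branch).
#'
#' @param target_trace Target Jacobian trace (1/ms); must be < 0.
#' @param target_det Target Jacobian determinant (1/ms^2); must be > 0.
#' @param theta_e,theta_i Activation thresholds, `theta_i > theta_e > 0`.
#' @param r_e_up,r_i_up Target UP-state rates (Hz), `r_i_up > r_e_up > 0`.
#' @param tau Rate time constant (ms).
#' @return An `isp_params` object reproducing the requested trace,
#'   determinant and UP rates to better than 1e-8.
#' @export
solve_pair_weights <- function(target_trace, target_det, theta_e, theta_i,
                               r_e_up, r_i_up, tau = 10) {
  if (!(target_trace < 0 && target_det > 0))
    stop("target (trace, det) must lie in the stable region: trace < 0, det > 0",
         call. = FALSE)
  if (!(r_i_up > r_e_up && r_e_up > 0))
    stop("UP rates must satisfy r_i_up > r_e_up > 0", call. = FALSE)
  S <- tau * target_trace + 2          # w_ee + w_ii
  D <- tau^2 * target_det              # (w_ee-1)(w_ii-1) - w_ei*w_ie
  # remaining weights as linear functions of a = w_ee:
  #   w_ii = S - a
  #   w_ie = (theta_e - (a - 1) r_e) / r_i     (E nullcline through UP)
  #   w_ei = (theta_i - (S - a - 1) r_i) / r_e (I nullcline through UP)
  resid <- function(a) {
    wii <- S - a
    wie <- (theta_e - (a - 1) * r_e_up) / r_i_up
    wei <- (theta_i - (wii - 1) * r_i_up) / r_e_up
    (a - 1) * (wii - 1) - wei * wie - D
  }
  # resid is exactly quadratic in a; recover its coefficients from 3 points
  y0 <- resid(0); y1 <- resid(1); y2 <- resid(2)
  c2 <- (y2 - 2 * y1 + y0) / 2
  c1 <- y1 - y0 - c2
  c0 <- y0
  if (abs(c2) < 1e-12) {
    if (abs(c1) < 1e-12)
      stop("root search failed to converge: degenerate weight system",
           call. = FALSE)
    roots <- -c0 / c1
  } else {
    disc <- c1^2 - 4 * c2 * c0
    if (disc < 0)
      stop("root search failed to converge: no real weight solution for this ",
           "(trace, det, thresholds, rates) combination", call. = FALSE)
    roots <- c((-c1 + sqrt(disc)) / (2 * c2), (-c1 - sqrt(disc)) / (2 * c2))
  }
  cands <- lapply(roots, function(a) {
    wii <- S - a
    list(w_ee = a,
         w_ie = (theta_e - (a - 1) * r_e_up) / r_i_up,
         w_ei = (theta_i - (wii - 1) * r_i_up) / r_e_up,
         w_ii = wii)
  })
  ok <- vapply(cands, function(w)
    w$w_ee >= 0 && w$w_ei >= 0 && w$w_ie <= 0 && w$w_ii <= 0, logical(1))
  if (!any(ok))
    stop("weight solution violates Dale's law sign constraints", call. = FALSE)
  keep <- cands[ok]
  w <- keep[[which.max(vapply(keep, `[[`, numeric(1), "w_ee"))]]
  out <- isp_params(w$w_ee, w$w_ie, w$w_ei, w$w_ii, theta_e, theta_i)
  # defensive round-trip check at the promised tolerance
  js <- jacobian_summary(out, tau)
  fp <- fixed_point_up(out)
  if (abs(js$trace - target_trace) > 1e-8 ||
      abs(js$determinant - target_det) > 1e-8 ||
      abs(fp$r_e - r_e_up) > 1e-8 || abs(fp$r_i - r_i_up) > 1e-8)
    stop("root search failed to converge: residuals exceed 1e-8", call. = FALSE)
  out
}
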