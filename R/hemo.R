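# Core hemodynamic model: simplified Bernoulli mapping, Weiss mono-exponential
# left-ventricular relaxation, the two-interval LAP equation system and its
# solver, and the sphygmomanometer (blood-pressure) LAP estimate.
#
# Units are fixed throughout the package: seconds, m/s, mmHg.

# Feasible range of the interval ratio (t1 - t3) / (t1 - t2).  The lower bound
# is attained at LAP = 0 (ln 9 / ln 4); the upper bound 8/3 is the LAP -> Inf
# limit and is never attained.
RATIO_MIN <- log(9) / log(4)
RATIO_MAX <- 8 / 3

#' Simplified Bernoulli pressure difference
#'
#' Maps a regurgitant jet velocity to the instantaneous pressure difference
#' across the mitral valve, `dp = 4 v^2`.  At the descending-branch landmark
#' speeds 1, 2 and 3 m/s this gives the 4, 16 and 36 mmHg offsets that enter
#' the two-interval LAP equation system.
#'
#' @param v Jet velocity in m/s (vector allowed); must be non-negative.
#' @return Pressure difference in mmHg, same length as `v`.
#' @examples
#' bernoulli_dp(3)  # 36 mmHg
#' @export
bernoulli_dp <- function(v) {
  if (!is.numeric(v) || length(v) == 0L || any(!is.finite(v))) {
    mrlap_error("`v` must be finite numeric", "mrlap_domain_error")
  }
  if (any(v < 0)) {
    mrlap_error("jet velocity must be non-negative", "mrlap_domain_error")
  }
  4 * v^2
}

#' Weiss mono-exponential pressure decay
#'
#' `weiss_decay()` bundles the parameters of the isovolumic-relaxation model
#' `P(t) = p_ref * exp(-(t - t_ref) / tau)`; `weiss_pressure()` evaluates it.
#' Time is measured from the instant of peak pressure-decline rate
#' (-dP/dt max), which is the model's reference time.
#'
#' @param p_ref Left-ventricular pressure at the reference time (mmHg, > 0).
#' @param tau Relaxation time constant (s, > 0).
#' @param t_ref Reference time (s, default 0).
#' @return `weiss_decay()` returns an object of class `"weiss_decay"`.
#' @examples
#' d <- weiss_decay(p_ref = 100, tau = 0.05)
#' weiss_pressure(d, 0.05)  # one time constant: 100 / e
#' @export
weiss_decay <- function(p_ref, tau, t_ref = 0) {
  stopifnot_scalar(p_ref, "p_ref")
  stopifnot_scalar(tau, "tau")
  stopifnot_scalar(t_ref, "t_ref")
  if (p_ref <= 0) mrlap_error("`p_ref` must be > 0", "mrlap_domain_error")
  if (tau <= 0) mrlap_error("`tau` must be > 0", "mrlap_domain_error")
  structure(list(p_ref = p_ref, tau = tau, t_ref = t_ref),
            class = "weiss_decay")
}

#' @rdname weiss_decay
#' @param decay A `"weiss_decay"` object.
#' @param t Time(s) at which to evaluate, each `>= t_ref`.
#' @export
weiss_pressure <- function(decay, t) {
  stopifnot(inherits(decay, "weiss_decay"))
  if (any(!is.finite(t)) || any(t < decay$t_ref)) {
    mrlap_error("`t` must be finite and >= the reference time",
                "mrlap_domain_error")
  }
  decay$p_ref * exp(-(t - decay$t_ref) / decay$tau)
}

#' Relaxation time constant from pressure and its decline rate
#'
#' Under mono-exponential decay the time constant is the ratio of the
#' instantaneous pressure to its (positive) decline rate, `tau = P / (-dP/dt)`.
#'
#' @param p Left-ventricular pressure (mmHg, > 0).
#' @param dpdt Pressure rate of change (mmHg/s); must be negative (declining).
#' @return Time constant tau in seconds.
#' @export
tau_from_pressure_rate <- function(p, dpdt) {
  stopifnot_scalar(p, "p")
  stopifnot_scalar(dpdt, "dpdt")
  if (p <= 0) mrlap_error("`p` must be > 0", "mrlap_domain_error")
  if (dpdt >= 0) {
    mrlap_error("`dpdt` must be negative (declining pressure)",
                "mrlap_domain_error")
  }
  p / (-dpdt)
}

#' Descending-branch landmark times
#'
#' Absolute times at which the descending branch of the mitral-regurgitation
#' envelope crosses 3, 2 and 1 m/s.  Velocity falls with time, so
#' `t3 < t2 < t1`.  Only the differences `t1 - t2` and `t1 - t3` enter the
#' LAP equations, so the time origin is arbitrary.
#'
#' @param t1,t2,t3 Crossing times (s) at 1, 2 and 3 m/s respectively.
#' @return An object of class `"descent_times"`.
#' @export
descent_times <- function(t1, t2, t3) {
  stopifnot_scalar(t1, "t1")
  stopifnot_scalar(t2, "t2")
  stopifnot_scalar(t3, "t3")
  if (any(c(t1, t2, t3) < 0)) {
    mrlap_error("descent times must be >= 0", "mrlap_domain_error")
  }
  if (!(t3 < t2 && t2 < t1)) {
    mrlap_error("descent times must satisfy t3 < t2 < t1 (velocity falls with time)",
                "mrlap_domain_error")
  }
  structure(list(t1 = t1, t2 = t2, t3 = t3), class = "descent_times")
}

#' @export
print.descent_times <- function(x, ...) {
  cat(sprintf("Descent times (s): t3 = %.6g (3 m/s), t2 = %.6g (2 m/s), t1 = %.6g (1 m/s)\n",
              x$t3, x$t2, x$t1))
  invisible(x)
}

#' Forward model: descent intervals from LAP and tau
#'
#' Inverse of the estimator: given a true left atrial pressure and relaxation
#' constant, returns the intervals between the landmark crossings,
#' `d13 = tau * ln((lap + 36)/(lap + 4))` and
#' `d12 = tau * ln((lap + 16)/(lap + 4))`.
#' Serves as the exact oracle for the solver round trip.
#'
#' @param lap Left atrial pressure (mmHg, >= 0).
#' @param tau Relaxation time constant (s, > 0).
#' @return List with `d12` (= t1 - t2) and `d13` (= t1 - t3), both seconds.
#' @export
forward_descent_intervals <- function(lap, tau) {
  stopifnot_scalar(lap, "lap")
  stopifnot_scalar(tau, "tau")
  if (lap < 0) mrlap_error("`lap` must be >= 0", "mrlap_domain_error")
  if (tau <= 0) mrlap_error("`tau` must be > 0", "mrlap_domain_error")
  list(d12 = tau * log((lap + 16) / (lap + 4)),
       d13 = tau * log((lap + 36) / (lap + 4)))
}

#' LAP estimate container
#'
#' @param lap Estimated left atrial pressure (mmHg).
#' @param method One of `"Eq"` (equation method), `"BP"` (sphygmomanometer
#'   method) or `"C"` (catheter reference).
#' @param tau Relaxation constant (s) for the equation method, else `NA`.
#' @param diagnostics Named list of solver diagnostics.
#' @param flags Character vector of quality flags (e.g. `"implausible_negative"`).
#' @return An object of class `"lap_estimate"`.
#' @export
lap_estimate <- function(lap, method, tau = NA_real_, diagnostics = list(),
                         flags = character()) {
  method <- match.arg(method, c("Eq", "BP", "C"))
  structure(list(lap = lap, tau = tau, method = method,
                 diagnostics = diagnostics, flags = flags),
            class = "lap_estimate")
}

#' @export
print.lap_estimate <- function(x, ...) {
  cat(sprintf("LAP_%s = %.3f mmHg", x$method, x$lap))
  if (is.finite(x$tau)) cat(sprintf(", tau = %.4f s", x$tau))
  if (length(x$flags)) cat(" [", paste(x$flags, collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Solve the two-interval equation system for LAP and tau
#'
#' The descending branch of the regurgitant jet obeys
#' `t1 - t3 = tau * ln((LAP + 36)/(LAP + 4))` and
#' `t1 - t2 = tau * ln((LAP + 16)/(LAP + 4))`:
#' two equations in the two unknowns LAP and tau.  Eliminating tau leaves a
#' single equation in LAP whose left side
#' `g(L) = ln((L+36)/(L+4)) / ln((L+16)/(L+4))` is strictly increasing from
#' `ln 9 / ln 4` at L = 0 towards `8/3`, so the root is unique when the
#' measured interval ratio lies in that range.  It is located by bisection,
#' then tau is recovered from the `t1 - t3` equation.
#'
#' @param times A [descent_times] object.
#' @param bracket Search interval for LAP in mmHg (default `c(0, 200)`).
#' @param tol Absolute convergence tolerance on LAP (mmHg, default 1e-8).
#' @param max_iter Maximum bisection iterations (default 200).
#' @param ratio_tol Slack allowed on the feasibility bounds of the interval
#'   ratio (default 1e-9); a ratio within `ratio_tol` below the lower bound is
#'   solved as LAP = 0.
#' @return A [lap_estimate] with `method = "Eq"`, the recovered `tau`, and
#'   diagnostics (`ratio`, `iterations`, `converged`, `residual`).
#' @seealso [forward_descent_intervals] for the exact inverse.
#' @export
solve_lap_eq <- function(times, bracket = c(0, 200), tol = 1e-8,
                         max_iter = 200L, ratio_tol = 1e-9) {
  stopifnot(inherits(times, "descent_times"))
  d12 <- times$t1 - times$t2
  d13 <- times$t1 - times$t3
  r <- d13 / d12

  if (r < RATIO_MIN - ratio_tol || r >= RATIO_MAX - ratio_tol) {
    mrlap_error(sprintf(
      "interval ratio (t1-t3)/(t1-t2) = %.6f outside the feasible range [%.6f, %.6f): no non-negative LAP solves the system",
      r, RATIO_MIN, RATIO_MAX), "mrlap_infeasible_geometry")
  }

  # h(L) = d12 * ln((L+36)/(L+4)) - d13 * ln((L+16)/(L+4)); h is proportional
  # to g(L) - r, so it crosses zero exactly at the solution.
  h <- function(L) d12 * log((L + 36) / (L + 4)) - d13 * log((L + 16) / (L + 4))

  lo <- bracket[1]
  hi <- bracket[2]
  h_lo <- h(lo)
  h_hi <- h(hi)

  if (h_lo >= 0) {
    # Ratio at (or within tolerance below) the LAP = 0 limit.
    lap <- lo
    iter <- 0L
    converged <- TRUE
  } else if (h_hi < 0) {
    mrlap_error(sprintf(
      "no root in LAP bracket [%g, %g]; interval ratio %.6f implies LAP above the bracket",
      lo, hi, r), "mrlap_convergence_error")
  } else {
    iter <- 0L
    converged <- FALSE
    while (iter < max_iter) {
      iter <- iter + 1L
      mid <- (lo + hi) / 2
      if (h(mid) < 0) lo <- mid else hi <- mid
      if ((hi - lo) <= tol) {
        converged <- TRUE
        break
      }
    }
    lap <- (lo + hi) / 2
    if (!converged) {
      mrlap_error(sprintf("bisection did not converge in %d iterations", max_iter),
                  "mrlap_convergence_error")
    }
  }

  tau <- d13 / log((lap + 36) / (lap + 4))
  lap_estimate(
    lap = lap, method = "Eq", tau = tau,
    diagnostics = list(ratio = r, iterations = iter, converged = converged,
                       residual = h(lap)))
}

#' Sphygmomanometer LAP estimate
#'
#' In the absence of aortic or outflow-tract stenosis the arterial systolic
#' pressure stands in for the left-ventricular systolic pressure, so
#' `LAP_BP = P_systolic - 4 * v_peak^2` with `v_peak` the peak regurgitant
#' velocity.  A negative result is physiologically implausible (typically a
#' sign of eccentric-jet velocity underestimation) and is returned with the
#' flag `"implausible_negative"` rather than clipped, so that downstream
#' comparison statistics see the raw value.
#'
#' @param p_systolic Arterial systolic pressure (mmHg, > 0).
#' @param v_peak Peak mitral-regurgitation velocity (m/s, > 0).
#' @return A [lap_estimate] with `method = "BP"` and no tau.
#' @export
lap_bp <- function(p_systolic, v_peak) {
  stopifnot_scalar(p_systolic, "p_systolic")
  stopifnot_scalar(v_peak, "v_peak")
  if (p_systolic <= 0) mrlap_error("`p_systolic` must be > 0", "mrlap_domain_error")
  if (v_peak <= 0) mrlap_error("`v_peak` must be > 0", "mrlap_domain_error")
  lap <- p_systolic - bernoulli_dp(v_peak)
  flags <- character()
  if (lap < 0) {
    flags <- "implausible_negative"
    mrlap_warn(sprintf("LAP_BP = %.2f mmHg is negative (physiologically implausible)", lap),
               "mrlap_implausible_value")
  }
  lap_estimate(lap = lap, method = "BP", flags = flags)
}
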