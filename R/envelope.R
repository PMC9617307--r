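# Envelope extraction: column-wise coarse edge detection, robust polynomial
# refinement, calculability rules, and landmark-crossing extraction.

#' Maximal-velocity envelope trace
#'
#' Per-time-frame maximal jet speed with validity flags.  Velocities are
#' magnitudes in m/s; `time` is strictly increasing with constant spacing.
#'
#' @param time Per-column time stamps (s).
#' @param velocity Per-column maximal jet speed (m/s, >= 0).
#' @param valid Per-column logical validity flag.
#' @return An object of class `"envelope_trace"`.
#' @export
envelope_trace <- function(time, velocity, valid = rep(TRUE, length(time))) {
  if (length(time) != length(velocity) || length(time) != length(valid)) {
    mrlap_error("time, velocity and valid must have equal length", "mrlap_domain_error")
  }
  if (length(time) == 0L) {
    mrlap_error("envelope must be non-empty", "mrlap_domain_error")
  }
  if (any(diff(time) <= 0)) {
    mrlap_error("time must be strictly increasing", "mrlap_domain_error")
  }
  if (any(velocity < 0, na.rm = TRUE)) {
    mrlap_error("velocities must be >= 0", "mrlap_domain_error")
  }
  structure(list(time = as.numeric(time), velocity = as.numeric(velocity),
                 valid = as.logical(valid)),
            class = "envelope_trace")
}

#' @export
print.envelope_trace <- function(x, ...) {
  cat(sprintf("Envelope trace: %d frames over %.3f s, peak %.2f m/s, %d invalid\n",
              length(x$time), diff(range(x$time)),
              suppressWarnings(max(x$velocity[x$valid], na.rm = TRUE)),
              sum(!x$valid)))
  invisible(x)
}

#' Coarse envelope detection from a spectrogram
#'
#' For each time frame, the envelope is the outermost jet-side pixel whose
#' intensity exceeds a global threshold, converted to a velocity magnitude via
#' the row calibration.  The default threshold is Otsu's bimodal-histogram
#' criterion (the jet and the background form the two modes); a fixed absolute
#' threshold can be supplied instead.
#'
#' Columns with no above-threshold pixel are flagged invalid (velocity 0).
#' Columns whose jet reaches the last row of the velocity axis are flagged
#' invalid as saturated: the true maximum is off-scale.
#'
#' @param spec A [calibrate_pixels] spectrogram.
#' @param threshold `"otsu"` or a fixed numeric intensity threshold.
#' @return An [envelope_trace].
#' @export
detect_raw_edge <- function(spec, threshold = "otsu") {
  stopifnot(inherits(spec, "spectrogram"))
  img <- spec$intensity
  if (max(img) <= 0) {
    mrlap_error("spectrogram carries no signal (all-zero image)", "mrlap_empty_signal")
  }
  thr <- if (identical(threshold, "otsu")) {
    rng <- range(img)
    if (diff(rng) == 0) {
      rng[1] / 2  # degenerate uniform image: everything is "signal"
    } else {
      EBImage::otsu(img, range = rng)
    }
  } else {
    stopifnot_scalar(threshold, "threshold")
    threshold
  }

  rows <- jet_rows(spec)
  vels <- jet_velocities(spec)
  sub <- img[rows, , drop = FALSE]     # row i of sub has velocity vels[i]
  mask <- sub > thr
  nr <- nrow(sub)

  outer_idx <- apply(mask, 2, function(col) {
    i <- which(col)
    if (length(i)) max(i) else NA_integer_
  })

  valid <- !is.na(outer_idx)
  saturated <- valid & outer_idx == nr
  velocity <- ifelse(valid, vels[pmax(outer_idx, 1L)], 0)
  valid <- valid & !saturated

  if (!any(valid) && !any(saturated)) {
    mrlap_error("no pixel above the detection threshold", "mrlap_empty_signal")
  }

  env <- envelope_trace(time = (seq_len(ncol(img)) - 1L) * spec$dt,
                        velocity = velocity, valid = valid)
  attr(env, "threshold") <- thr
  attr(env, "saturated") <- saturated
  env
}

# Robust polynomial fit on (t, y): least squares, then rejection of
# residuals beyond mad_mult * MAD, refit.  Returns predictions at `t_out`.
#' @noRd
robust_polyfit <- function(t, y, degree, t_out, passes = 2L, mad_mult = 3) {
  keep <- rep(TRUE, length(t))
  deg <- min(degree, length(unique(t)) - 1L)
  fit <- NULL
  for (pass in seq_len(max(passes, 1L))) {
    deg_k <- min(deg, length(unique(t[keep])) - 1L)
    fit <- if (deg_k >= 1L) {
      stats::lm(y ~ stats::poly(t, deg_k, raw = FALSE),
                data = data.frame(t = t[keep], y = y[keep]))
    } else {
      stats::lm(y ~ 1, data = data.frame(t = t[keep], y = y[keep]))
    }
    if (pass == passes) break
    res <- y - as.numeric(stats::predict(fit, newdata = data.frame(t = t)))
    s <- stats::mad(res[keep])
    if (s == 0) break
    keep_new <- abs(res) <= mad_mult * s
    # never drop below the points needed for the fit
    if (sum(keep_new) < deg + 1L) break
    keep <- keep_new
  }
  as.numeric(stats::predict(fit, newdata = data.frame(t = t_out)))
}

#' Polynomial refinement of a raw envelope
#'
#' Coarse column-wise detection leaves dislocations (isolated spikes) and
#' fractures (gaps of invalid columns).  Refinement replaces the trace with a
#' smooth piecewise-polynomial least-squares fit: the beat is split at the
#' velocity peak and the ascending and descending limbs are each fit
#' separately, with robust re-weighting (residuals beyond `mad_mult` times
#' the MAD are rejected and the limb refit).  Invalid columns are filled with
#' the fitted value, so the output is valid everywhere.
#'
#' The fit is performed on the squared velocity (the Bernoulli-mapped
#' transmitral gradient, up to the factor 4), where the descending branch is
#' a shifted exponential and free of the square-root steepening that the
#' velocity trace shows near zero; a polynomial of degree `2 * degree` is
#' used there, so any velocity envelope that is itself a polynomial of degree
#' up to `degree` is reproduced exactly and the refinement is idempotent.
#' The split point is located on a running-median-smoothed trace so that a
#' single-column spike cannot masquerade as the beat peak.
#'
#' A coarse trace from a pixel detector is a staircase: runs of columns
#' share one quantized velocity level.  Fitting such runs directly biases
#' the least squares towards the level centers, so when a limb is
#' staircase-like (a substantial share of consecutive equal values) the fit
#' uses the level-crossing points instead: at every transition between
#' adjacent columns the true envelope crosses the departing level at the
#' column boundary, giving support points with exact ordinate and timing
#' error of at most half a frame.
#'
#' @param raw An [envelope_trace] from [detect_raw_edge].
#' @param degree Polynomial degree per limb, in velocity terms (default 4).
#' @param passes Robust fitting passes (default 2: one rejection round).
#' @param mad_mult Residual rejection multiple in MADs (default 3).
#' @param spike_tol Excess (m/s) of the raw maximum over the smoothed maximum
#'   above which the raw peak is treated as a spike when locating the split
#'   (default 0.3).
#' @return A refined [envelope_trace] with all columns valid.
#' @export
refine_edge_polynomial <- function(raw, degree = 4L, passes = 2L, mad_mult = 3,
                                   spike_tol = 0.3) {
  stopifnot(inherits(raw, "envelope_trace"))
  ok <- raw$valid
  if (sum(ok) < degree + 1L) {
    mrlap_error(sprintf("too few valid columns (%d) for degree-%d refinement",
                        sum(ok), degree), "mrlap_refinement_error")
  }
  t <- raw$time
  v <- raw$velocity
  tv <- t[ok]
  vv <- v[ok]
  wv <- vv^2  # squared-velocity (gradient-proportional) domain

  # Peak location for the limb split, robust to single-column spikes.
  k <- min(5L, length(vv) - (1 - length(vv) %% 2L))
  vs <- if (k >= 3L) stats::runmed(vv, k) else vv
  p <- if (max(vv) - max(vs) > spike_tol) which.max(vs) else which.max(vv)

  n <- length(t)
  peak_t <- tv[p]
  asc_cols <- which(t < peak_t)
  desc_cols <- which(t >= peak_t)
  wdeg <- 2L * degree

  # Replace a staircase limb by its level-crossing points (see Details).
  limb_points <- function(tt, vv) {
    if (length(tt) < 3L) return(list(t = tt, w = vv^2))
    eq <- vv[-1] == vv[-length(vv)]
    trans <- which(!eq)
    if (mean(eq) > 0.2 && length(trans) >= wdeg + 1L) {
      list(t = (tt[trans] + tt[trans + 1L]) / 2,
           w = pmax(vv[trans], vv[trans + 1L])^2)
    } else {
      list(t = tt, w = vv^2)
    }
  }

  out <- numeric(n)
  if (length(asc_cols) > 0L && p > 1L) {
    pts <- limb_points(tv[seq_len(p - 1L)], vv[seq_len(p - 1L)])
    out[asc_cols] <- robust_polyfit(pts$t, pts$w, wdeg, t[asc_cols],
                                    passes, mad_mult)
  } else if (length(asc_cols) > 0L) {
    out[asc_cols] <- wv[p]
  }
  pts <- limb_points(tv[p:length(tv)], vv[p:length(vv)])
  out[desc_cols] <- robust_polyfit(pts$t, pts$w, wdeg, t[desc_cols],
                                   passes, mad_mult)
  out <- sqrt(pmax(out, 0))

  env <- envelope_trace(time = t, velocity = out, valid = rep(TRUE, n))
  attr(env, "filled") <- !ok
  env
}

#' Envelope quality and calculability assessment
#'
#' Encodes the method's calculability rules: the estimate is computed only
#' when the descending branch is complete — after the peak the envelope falls
#' (monotonically, within a small tolerance band that absorbs residual
#' roughness) through 3, 2 and 1 m/s before the trace ends — and the peak
#' velocity is at least 3 m/s.
#'
#' @param env An [envelope_trace].
#' @param tol Monotonicity tolerance band in m/s (default 0.15): a frame may
#'   rise by at most this much and the descent still counts as monotone.
#' @return An object of class `"envelope_quality"` with fields
#'   `peak_velocity`, `has_complete_descent`, `descent_gap_count`,
#'   `calculable` and `failed_rules`.
#' @export
assess_quality <- function(env, tol = 0.15) {
  stopifnot(inherits(env, "envelope_trace"))
  v <- env$velocity
  v[!env$valid] <- NA_real_
  if (all(is.na(v))) {
    mrlap_error("envelope has no valid columns", "mrlap_empty_signal")
  }
  peak_velocity <- max(v, na.rm = TRUE)
  ip <- which.max(ifelse(is.na(v), -Inf, v))

  post <- v[ip:length(v)]
  gaps_region <- post
  reaches_1 <- any(post <= 1, na.rm = TRUE)
  monotone <- TRUE
  if (reaches_1) {
    k <- which(post <= 1)[1]
    seg <- post[1:k]
    gaps_region <- seg
    segv <- seg[!is.na(seg)]
    monotone <- all(diff(segv) <= tol)
  }
  has_complete_descent <- reaches_1 && monotone
  descent_gap_count <- sum(is.na(gaps_region))

  failed <- character()
  if (peak_velocity < 3) failed <- c(failed, "peak below 3 m/s")
  if (!has_complete_descent) failed <- c(failed, "incomplete descending branch")

  structure(list(peak_velocity = peak_velocity,
                 has_complete_descent = has_complete_descent,
                 descent_gap_count = descent_gap_count,
                 calculable = length(failed) == 0L,
                 failed_rules = failed),
            class = "envelope_quality")
}

#' @export
print.envelope_quality <- function(x, ...) {
  cat(sprintf("Envelope quality: peak %.2f m/s, complete descent: %s, gaps: %d\n",
              x$peak_velocity, x$has_complete_descent, x$descent_gap_count))
  cat(if (x$calculable) "  calculable\n"
      else paste0("  NOT calculable: ", paste(x$failed_rules, collapse = "; "), "\n"))
  invisible(x)
}

#' Extract the descending-branch landmark times
#'
#' Locates, after the global velocity peak, the first downward crossing of
#' each landmark speed (3, 2, 1 m/s) by linear interpolation between the
#' bracketing frames, giving sub-frame precision.  Refuses to run when the
#' calculability rules fail, naming the violated rule.
#'
#' When the raw (pre-refinement) trace is supplied, each crossing found on
#' `env` is then re-localized on the raw samples by a robust local quadratic
#' fit of the squared velocity inside a window around the bracket.  The
#' global polynomial smooths away sub-pixel information exactly where the
#' landmark crossings sit; the local fit averages the pixel quantization of
#' two dozen raw columns instead and is accurate to a fraction of a pixel.
#' If the local fit finds no crossing (e.g. too few valid columns), the
#' interpolated time from `env` is kept.
#'
#' @param env An [envelope_trace] (normally refined).
#' @param quality Optional precomputed [assess_quality] result.
#' @param raw Optional raw [envelope_trace] from [detect_raw_edge] for
#'   sub-pixel crossing re-localization.
#' @param window Half-width (s) of the local re-localization window
#'   (default 0.012).
#' @return A [descent_times] object.
#' @export
extract_descent_times <- function(env, quality = assess_quality(env),
                                  raw = NULL, window = 0.012) {
  stopifnot(inherits(env, "envelope_trace"))
  if (!quality$calculable) {
    mrlap_error(paste("envelope not calculable:",
                      paste(quality$failed_rules, collapse = "; ")),
                "mrlap_rule_violation")
  }
  v <- env$velocity
  t <- env$time
  ip <- which.max(v)

  cross_time <- function(target) {
    for (i in ip:(length(v) - 1L)) {
      if (v[i] >= target && v[i + 1L] < target) {
        # linear interpolation between the bracketing frames
        return(t[i] + (v[i] - target) / (v[i] - v[i + 1L]) * (t[i + 1L] - t[i]))
      }
    }
    NA_real_
  }

  t3 <- cross_time(3)
  t2 <- cross_time(2)
  t1 <- cross_time(1)
  if (anyNA(c(t1, t2, t3))) {
    mrlap_error("descending branch does not cross all of 3, 2 and 1 m/s",
                "mrlap_rule_violation")
  }
  if (!is.null(raw)) {
    stopifnot(inherits(raw, "envelope_trace"))
    r3 <- local_crossing(raw, t3, 3, window)
    r2 <- local_crossing(raw, t2, 2, window)
    r1 <- local_crossing(raw, t1, 1, window)
    if (!anyNA(c(r1, r2, r3)) && r3 < r2 && r2 < r1) {
      t1 <- r1; t2 <- r2; t3 <- r3
    }
  }
  descent_times(t1 = t1, t2 = t2, t3 = t3)
}

# Sub-pixel re-localization of a downward crossing of `target` (m/s) near
# t_bracket: robust local quadratic fit of the squared velocity on the raw
# samples within the window, then the crossing of the fitted curve closest
# to the bracket.
#' @noRd
local_crossing <- function(raw, t_bracket, target, window) {
  ok <- raw$valid & abs(raw$time - t_bracket) <= window
  if (sum(ok) < 6L) return(NA_real_)
  tt <- raw$time[ok]
  ww <- raw$velocity[ok]^2
  wstar <- target^2
  keep <- rep(TRUE, length(tt))
  fit <- NULL
  for (pass in 1:2) {
    fit <- stats::lm(w ~ stats::poly(t, 2),
                     data = data.frame(t = tt[keep], w = ww[keep]))
    res <- ww - as.numeric(stats::predict(fit, newdata = data.frame(t = tt)))
    s <- stats::mad(res[keep])
    if (s == 0) break
    keep_new <- abs(res) <= 3 * s
    if (sum(keep_new) < 6L) break
    keep <- keep_new
  }
  tg <- seq(min(tt), max(tt), length.out = 400L)
  wg <- as.numeric(stats::predict(fit, newdata = data.frame(t = tg)))
  i <- which(wg[-length(wg)] >= wstar & wg[-1] < wstar)
  if (!length(i)) return(NA_real_)
  i <- i[which.min(abs(tg[i] - t_bracket))]
  tg[i] + (wg[i] - wstar) / (wg[i] - wg[i + 1L]) * (tg[i + 1L] - tg[i])
}
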