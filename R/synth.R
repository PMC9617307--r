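# Ground-truthed synthetic cohort generation: hemodynamic truths, model-exact
# velocity envelopes, speckled spectrogram rendering, and simulated catheter
# and arterial readings.

#' Ground-truth hemodynamics of a synthetic patient
#'
#' @param lap_true True left atrial pressure (mmHg).
#' @param tau Relaxation time constant (s), within \[0.02, 0.12\].
#' @param v_peak Peak regurgitant velocity (m/s).
#' @param p_systolic Systolic (left-ventricular = arterial, absent outflow
#'   stenosis) pressure (mmHg); default is the model-consistent
#'   `lap_true + 4 v_peak^2`.
#' @param eccentricity_factor Velocity underestimation factor `c` in (0, 1]
#'   (cosine of the Doppler intercept angle).  Must be 1 except for the
#'   eccentric-jet group `"MVP_P1P3"`.
#' @param group Disease group: `"CABG"`, `"RHD"`, `"MVP_A2P2"` or
#'   `"MVP_P1P3"` (the eccentric-jet prolapse group).
#' @param rhythm `"sinus"` or `"AF"`.
#' @return An object of class `"patient_truth"`.
#' @export
patient_truth <- function(lap_true, tau, v_peak,
                          p_systolic = lap_true + 4 * v_peak^2,
                          eccentricity_factor = 1,
                          group = c("CABG", "RHD", "MVP_A2P2", "MVP_P1P3"),
                          rhythm = c("sinus", "AF")) {
  group <- match.arg(group)
  rhythm <- match.arg(rhythm)
  stopifnot_scalar(lap_true, "lap_true")
  stopifnot_scalar(tau, "tau")
  stopifnot_scalar(v_peak, "v_peak")
  stopifnot_scalar(p_systolic, "p_systolic")
  stopifnot_scalar(eccentricity_factor, "eccentricity_factor")
  if (lap_true <= 0) mrlap_error("`lap_true` must be > 0", "mrlap_domain_error")
  if (tau < 0.02 || tau > 0.12) {
    mrlap_error("`tau` must lie in [0.02, 0.12] s", "mrlap_domain_error")
  }
  if (v_peak <= 0) mrlap_error("`v_peak` must be > 0", "mrlap_domain_error")
  if (eccentricity_factor <= 0 || eccentricity_factor > 1) {
    mrlap_error("`eccentricity_factor` must be in (0, 1]", "mrlap_domain_error")
  }
  if (eccentricity_factor < 1 && group != "MVP_P1P3") {
    mrlap_error("eccentric jets (c < 1) are modeled only for group 'MVP_P1P3'",
                "mrlap_domain_error")
  }
  structure(list(lap_true = lap_true, tau = tau, v_peak = v_peak,
                 p_systolic = p_systolic,
                 eccentricity_factor = eccentricity_factor,
                 group = group, rhythm = rhythm),
            class = "patient_truth")
}

#' Model-exact regurgitant velocity envelope
#'
#' Builds the measured MR velocity envelope of one beat from the pressure
#' model.  The ascending limb is a half-cosine rise of LV pressure from
#' `lap_true` to the peak pressure `lap_true + 4 v_peak^2` over `t_rise`
#' (cosmetic: only the descending branch enters the estimator).  The
#' descending limb follows Weiss decay `P(t) = P_peak exp(-(t - t_peak)/tau)`
#' until `P <= lap_true + p_end_eps`.  Velocity is
#' `sqrt(P - lap_true) / 2` (inverse simplified Bernoulli) and all measured
#' velocities are multiplied by the eccentricity factor `c`.
#'
#' @param truth A [patient_truth].
#' @param dt Frame spacing in seconds (default 0.001).
#' @param t_rise Ascending-limb duration (s, default 0.1).
#' @param p_end_eps Transmitral gradient (mmHg) at which the rendered beat
#'   ends (default 0.25, i.e. the envelope tails off at 0.25 m/s).
#' @return An [envelope_trace]; attribute `"t_peak"` holds the peak time.
#' @export
simulate_envelope <- function(truth, dt = 0.001, t_rise = 0.1, p_end_eps = 0.25) {
  stopifnot(inherits(truth, "patient_truth"))
  if (dt <= 0) mrlap_error("`dt` must be > 0", "mrlap_domain_error")
  if (truth$p_systolic <= truth$lap_true) {
    mrlap_error("systolic pressure must exceed LAP (no regurgitant gradient)",
                "mrlap_infeasible_physiology")
  }
  lap <- truth$lap_true
  p_peak <- lap + 4 * truth$v_peak^2
  t_end <- t_rise + truth$tau * log(p_peak / (lap + p_end_eps))
  tt <- seq(0, t_end, by = dt)

  p_lv <- ifelse(tt < t_rise,
                 lap + (p_peak - lap) * (1 - cos(pi * tt / t_rise)) / 2,
                 p_peak * exp(-(tt - t_rise) / truth$tau))
  dp <- pmax(p_lv - lap, 0)
  v <- truth$eccentricity_factor * sqrt(dp) / 2

  env <- envelope_trace(time = tt, velocity = v)
  attr(env, "t_peak") <- t_rise
  env
}

#' Rendering noise configuration
#'
#' @param speckle_var Variance of the unit-mean multiplicative speckle
#'   (gamma-distributed; 0 disables).
#' @param background_sd Spread of the additive half-normal background noise.
#' @param soft_edge_px Width (pixels) of the linear intensity taper below the
#'   envelope edge (0 = hard edge).
#' @param base_intensity Fill intensity of the jet before noise.
#' @return A noise-configuration list.
#' @export
render_noise <- function(speckle_var = 0.1, background_sd = 0.02,
                         soft_edge_px = 2, base_intensity = 0.8) {
  if (speckle_var < 0 || background_sd < 0 || soft_edge_px < 0) {
    mrlap_error("noise parameters must be >= 0", "mrlap_domain_error")
  }
  list(speckle_var = speckle_var, background_sd = background_sd,
       soft_edge_px = soft_edge_px, base_intensity = base_intensity)
}

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
#' @noRd
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Render an envelope into a speckled CW-Doppler spectrogram
#'
#' Pixels between the zero-velocity baseline (row 1, jet below) and the
#' envelope are filled with the base intensity, tapered linearly over the
#' soft-edge width, multiplied by unit-mean gamma speckle and overlaid with
#' half-normal background noise; intensities are clipped to \[0, 1\].
#' Rendering is deterministic under a fixed `seed`.
#'
#' @param env An [envelope_trace].
#' @param dv Velocity per row (m/s, default 0.01).
#' @param noise A [render_noise] configuration.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param headroom Fraction of velocity axis left above the peak (default 0.15).
#' @return A [calibrate_pixels] spectrogram.
#' @export
render_spectrogram <- function(env, dv = 0.01, noise = render_noise(),
                               seed = NULL, headroom = 0.15) {
  stopifnot(inherits(env, "envelope_trace"))
  if (dv <= 0) mrlap_error("`dv` must be > 0", "mrlap_domain_error")
  v_axis_max <- max(env$velocity) * (1 + headroom)
  n_rows <- max(ceiling(v_axis_max / dv) + 1L, 2L)
  n_cols <- length(env$time)
  row_v <- (seq_len(n_rows) - 1L) * dv

  with_local_seed(seed, {
    # fill fraction per (row, column): 1 deep inside the jet, tapering to 0
    # across soft_edge_px rows below the envelope edge
    if (noise$soft_edge_px > 0) {
      w <- noise$soft_edge_px * dv
      fill <- outer(row_v, env$velocity, function(rv, ev) pmin(pmax((ev - rv) / w, 0), 1))
    } else {
      fill <- outer(row_v, env$velocity, function(rv, ev) as.numeric(rv <= ev))
    }
    img <- noise$base_intensity * fill
    if (noise$speckle_var > 0) {
      shape <- 1 / noise$speckle_var
      speckle <- matrix(stats::rgamma(n_rows * n_cols, shape = shape, scale = 1 / shape),
                        n_rows, n_cols)
      img <- img * speckle
    }
    if (noise$background_sd > 0) {
      img <- img + abs(matrix(stats::rnorm(n_rows * n_cols, 0, noise$background_sd),
                              n_rows, n_cols))
    }
    img <- pmin(pmax(img, 0), 1)
    dt <- env$time[2] - env$time[1]
    calibrate_pixels(img, dt = dt, dv = dv, baseline_row = 1L, jet_side = "below")
  })
}

#' Simulated floating-catheter wedge-pressure reading
#'
#' The pulmonary arteriolar wedge pressure read at the end of the ECG P wave
#' is emulated as an unbiased noisy reading of the true LAP.
#'
#' @param truth A [patient_truth].
#' @param sigma_c Catheter reading spread (mmHg, >= 0; default 2).
#' @param seed Optional integer seed.
#' @return Simulated catheter LAP (mmHg).
#' @export
simulate_catheter <- function(truth, sigma_c = 2, seed = NULL) {
  stopifnot(inherits(truth, "patient_truth"))
  if (sigma_c < 0) mrlap_error("`sigma_c` must be >= 0", "mrlap_domain_error")
  with_local_seed(seed, truth$lap_true + stats::rnorm(1, 0, sigma_c))
}

#' Cohort generation configuration
#'
#' Defaults emulate the study conditions: LAP spanning 7--29 mmHg, peak
#' velocities 4.2--5 m/s (hence systolic pressures of roughly 78--129 mmHg),
#' and a disease mix of 10/28 surgical/rheumatic patients with central jets,
#' 7/28 central-jet prolapse (A2/P2) and 11/28 eccentric-jet prolapse (P1/P3)
#' whose measured velocity is scaled by `c` in \[0.85, 0.95\].
#'
#' @param n Number of patients (>= 1).
#' @param mix Named group proportions summing to 1.
#' @param lap_range,tau_range,v_peak_range Uniform sampling ranges.
#' @param c_range Eccentricity factor range for group `"MVP_P1P3"`.
#' @param af_prop Proportion of atrial fibrillation (modeled as a ±10 percent
#'   beat-level jitter of tau and peak velocity).
#' @param noise A [render_noise] configuration.
#' @param sigma_catheter Catheter reading spread (mmHg).
#' @param sigma_arterial Radial-artery systolic reading spread (mmHg).
#' @param dt,dv Rendering calibration (s per column, m/s per row).
#' @param seed Master seed; all case-level randomness derives from it.
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(n = 28L,
                          mix = c(CABG = 7 / 28, RHD = 3 / 28,
                                  MVP_A2P2 = 7 / 28, MVP_P1P3 = 11 / 28),
                          lap_range = c(7, 29),
                          tau_range = c(0.03, 0.08),
                          v_peak_range = c(4.2, 5.0),
                          c_range = c(0.85, 0.95),
                          af_prop = 12 / 28,
                          noise = render_noise(),
                          sigma_catheter = 2,
                          sigma_arterial = 3,
                          dt = 0.001, dv = 0.01,
                          seed = 20201001L) {
  if (!is_scalar_number(n) || n < 1) {
    mrlap_error("`n` must be >= 1", "mrlap_config_error")
  }
  groups <- c("CABG", "RHD", "MVP_A2P2", "MVP_P1P3")
  if (is.null(names(mix)) || !all(names(mix) %in% groups) || any(mix < 0) ||
      abs(sum(mix) - 1) > 1e-8) {
    mrlap_error("`mix` must be non-negative proportions over the disease groups summing to 1",
                "mrlap_config_error")
  }
  if (af_prop < 0 || af_prop > 1) {
    mrlap_error("`af_prop` must be in [0, 1]", "mrlap_config_error")
  }
  structure(list(n = as.integer(n), mix = mix, lap_range = lap_range,
                 tau_range = tau_range, v_peak_range = v_peak_range,
                 c_range = c_range, af_prop = af_prop, noise = noise,
                 sigma_catheter = sigma_catheter, sigma_arterial = sigma_arterial,
                 dt = dt, dv = dv, seed = as.integer(seed)),
            class = "cohort_config")
}

# Deterministic largest-remainder allocation of n cases to the mix groups.
#' @noRd
allocate_groups <- function(n, mix) {
  raw <- n * mix
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  rep(names(mix), times = counts)
}

#' Generate a ground-truthed synthetic cohort
#'
#' Draws `n` patients (group counts allocated deterministically to match the
#' mix), simulates each patient's envelope, renders the spectrogram, and
#' simulates the catheter and radial-artery readings.  Every case carries its
#' own child seed derived from the master seed, so individual cases and whole
#' cohorts are exactly reproducible.
#'
#' @param cfg A [cohort_config].
#' @return A list of `"synthetic_case"` objects, each with fields `id`,
#'   `truth`, `envelope_true`, `spectrogram`, `lap_catheter`,
#'   `p_radial_measured` and `seed`.
#' @export
simulate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  groups <- allocate_groups(cfg$n, cfg$mix)

  lapply(seq_len(cfg$n), function(i) {
    seed_i <- child_seed(cfg$seed, i)
    with_local_seed(seed_i, {
      group <- groups[i]
      lap <- stats::runif(1, cfg$lap_range[1], cfg$lap_range[2])
      tau <- stats::runif(1, cfg$tau_range[1], cfg$tau_range[2])
      v_peak <- stats::runif(1, cfg$v_peak_range[1], cfg$v_peak_range[2])
      rhythm <- if (stats::runif(1) < cfg$af_prop) "AF" else "sinus"
      if (rhythm == "AF") {
        # beat-to-beat variability of the analyzed beat
        tau <- max(0.02, min(0.12, tau * stats::runif(1, 0.9, 1.1)))
        v_peak <- v_peak * stats::runif(1, 0.9, 1.1)
      }
      cc <- if (group == "MVP_P1P3") stats::runif(1, cfg$c_range[1], cfg$c_range[2]) else 1
      truth <- patient_truth(lap_true = lap, tau = tau, v_peak = v_peak,
                             eccentricity_factor = cc, group = group,
                             rhythm = rhythm)
      env <- simulate_envelope(truth, dt = cfg$dt)
      spec <- render_spectrogram(env, dv = cfg$dv, noise = cfg$noise)
      lap_c <- truth$lap_true + stats::rnorm(1, 0, cfg$sigma_catheter)
      p_rad <- truth$p_systolic + stats::rnorm(1, 0, cfg$sigma_arterial)
      structure(list(id = sprintf("case_%03d", i), truth = truth,
                     envelope_true = env, spectrogram = spec,
                     lap_catheter = lap_c, p_radial_measured = p_rad,
                     seed = seed_i),
                class = "synthetic_case")
    })
  })
}

#' Flatten a synthetic cohort's ground truth to a data frame
#'
#' @param cases A list of synthetic cases from [simulate_cohort].
#' @return One row per case with ids, truth fields, seeds and the simulated
#'   catheter/arterial readings.
#' @export
cohort_truth_table <- function(cases) {
  do.call(rbind, lapply(cases, function(cs) {
    data.frame(id = cs$id, group = cs$truth$group, rhythm = cs$truth$rhythm,
               lap_true = cs$truth$lap_true, tau = cs$truth$tau,
               v_peak = cs$truth$v_peak, p_systolic = cs$truth$p_systolic,
               eccentricity_factor = cs$truth$eccentricity_factor,
               lap_catheter = cs$lap_catheter,
               p_radial_measured = cs$p_radial_measured,
               seed = cs$seed)
  }))
}
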