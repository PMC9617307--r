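# Fixtures built in code: noiseless rendered cases, simple geometric
# spectrograms, and data with an exact prescribed sample correlation.

# A rendered, noiseless synthetic case with known hemodynamics.
noiseless_case <- function(lap, tau, v_peak = 4.9, dt = 0.001, dv = 0.01,
                           eccentricity = 1,
                           group = if (eccentricity < 1) "MVP_P1P3" else "CABG") {
  truth <- patient_truth(lap_true = lap, tau = tau, v_peak = v_peak,
                         eccentricity_factor = eccentricity, group = group)
  env <- simulate_envelope(truth, dt = dt)
  spec <- render_spectrogram(env, dv = dv, noise = render_noise(0, 0, 0), seed = 1)
  list(truth = truth, env = env, spec = spec)
}

# A spectrogram whose column j is filled from the baseline to heights[j]
# (m/s) at intensity `fill` on a zero background.
band_spectrogram <- function(heights, dv = 0.05, dt = 0.002, fill = 1.0,
                             n_rows = ceiling(max(heights) / dv) + 10L) {
  img <- vapply(heights, function(h) {
    col <- numeric(n_rows)
    col[(seq_len(n_rows) - 1L) * dv <= h] <- fill
    col
  }, numeric(n_rows))
  calibrate_pixels(img, dt = dt, dv = dv, baseline_row = 1L, jet_side = "below")
}

# Paired data of length n whose sample Pearson correlation is exactly r.
make_cor_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  e <- stats::resid(stats::lm(stats::rnorm(n) ~ x))
  xs <- as.numeric(scale(x))
  es <- as.numeric(scale(e))
  list(x = xs, y = r * xs + sqrt(1 - r^2) * es)
}

# Analytic forward intervals with eccentricity-modified Bernoulli offsets:
# a measured crossing at v* corresponds to a true gradient 4 (v*/c)^2.
eccentric_intervals <- function(lap, tau, c) {
  o <- c(4, 16, 36) / c^2
  list(d12 = tau * log((lap + o[2]) / (lap + o[1])),
       d13 = tau * log((lap + o[3]) / (lap + o[1])))
}
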