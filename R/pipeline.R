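# End-to-end estimation pipeline and batch commands: calibrate -> detect ->
# refine -> quality -> landmark times -> solve, with per-case robustness.

#' Estimate LAP from a single calibrated spectrogram
#'
#' Runs the full measurement pipeline on one spectrogram: coarse edge
#' detection, polynomial refinement, calculability assessment, landmark-time
#' extraction and the two-interval solve.  Non-calculable spectra yield a
#' skip reason instead of an estimate; the batch never crashes on one bad
#' image.
#'
#' @param spec A [calibrate_pixels] spectrogram.
#' @param id Case identifier carried into the result record.
#' @param threshold Detection threshold (see [detect_raw_edge]).
#' @param degree Refinement polynomial degree (see [refine_edge_polynomial]).
#' @param p_systolic Optional arterial systolic pressure (mmHg); when given,
#'   the sphygmomanometer estimate `LAP_BP` is computed from the measured
#'   peak velocity.
#' @return A one-row data frame (class `"result_record"` semantics): `id`,
#'   `t1`, `t2`, `t3`, `lap_eq`, `tau`, `v_peak`, `lap_bp`, `calculable`,
#'   `skip_reason`.
#' @export
estimate_lap <- function(spec, id = "case", threshold = "otsu", degree = 4L,
                         p_systolic = NA_real_) {
  rec <- data.frame(id = id, t1 = NA_real_, t2 = NA_real_, t3 = NA_real_,
                    lap_eq = NA_real_, tau = NA_real_, v_peak = NA_real_,
                    lap_bp = NA_real_, calculable = FALSE,
                    skip_reason = NA_character_, stringsAsFactors = FALSE)
  res <- tryCatch({
    raw <- detect_raw_edge(spec, threshold = threshold)
    env <- refine_edge_polynomial(raw, degree = degree)
    q <- assess_quality(env)
    rec$v_peak <- q$peak_velocity
    if (!is.na(p_systolic) && q$peak_velocity > 0) {
      bp <- suppressWarnings(lap_bp(p_systolic, q$peak_velocity))
      rec$lap_bp <- bp$lap
    }
    if (!q$calculable) {
      rec$skip_reason <- paste(q$failed_rules, collapse = "; ")
      return(rec)
    }
    times <- extract_descent_times(env, q, raw = raw)
    est <- solve_lap_eq(times)
    rec$t1 <- times$t1; rec$t2 <- times$t2; rec$t3 <- times$t3
    rec$lap_eq <- est$lap; rec$tau <- est$tau
    rec$calculable <- TRUE
    rec
  }, mrlap_error = function(e) {
    rec$skip_reason <- conditionMessage(e)
    rec
  })
  res
}

#' Batch LAP estimation over a directory of spectrogram images
#'
#' Processes every PNG/TIFF in `images_dir` through [estimate_lap].  The
#' calibration comes from a shared YAML file (`calib`) or, when `calib` is
#' `NULL`, from a per-image sidecar (`<image>.yaml`).  Unreadable images
#' produce an error record, never a crash.
#'
#' @param images_dir Directory of `.png`/`.tif(f)` images.
#' @param calib Optional shared calibration YAML path.
#' @param out_dir Optional output directory; when given, writes
#'   `estimates.csv` and one `<case>_envelope.csv` (time_s, velocity_mps) per
#'   calculable case.
#' @param arterial Optional data frame (`id`, `p_systolic`) enabling LAP_BP.
#' @param ... Passed to [estimate_lap].
#' @return Data frame of result records (possibly empty).
#' @export
cmd_estimate <- function(images_dir, calib = NULL, out_dir = NULL,
                         arterial = NULL, ...) {
  if (!dir.exists(images_dir)) {
    mrlap_error(sprintf("images directory not found: %s", images_dir),
                "mrlap_config_error")
  }
  files <- list.files(images_dir, pattern = "\\.(png|tif|tiff)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0L) {
    mrlap_warn(sprintf("no images found in %s", images_dir), "mrlap_empty_batch")
    return(data.frame())
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  recs <- lapply(files, function(f) {
    id <- sub("\\.[^.]+$", "", basename(f))
    p_sys <- NA_real_
    if (!is.null(arterial) && id %in% arterial$id) {
      p_sys <- arterial$p_systolic[match(id, arterial$id)]
    }
    tryCatch({
      spec <- if (is.null(calib)) read_spectrogram(f) else read_spectrogram(f, calib)
      rec <- estimate_lap(spec, id = id, p_systolic = p_sys, ...)
      if (!is.null(out_dir) && rec$calculable) {
        raw <- detect_raw_edge(spec)
        env <- refine_edge_polynomial(raw)
        utils::write.csv(
          data.frame(time_s = signif(env$time, 6),
                     velocity_mps = signif(env$velocity, 6)),
          file.path(out_dir, paste0(id, "_envelope.csv")), row.names = FALSE)
      }
      rec
    }, error = function(e) {
      data.frame(id = id, t1 = NA_real_, t2 = NA_real_, t3 = NA_real_,
                 lap_eq = NA_real_, tau = NA_real_, v_peak = NA_real_,
                 lap_bp = NA_real_, calculable = FALSE,
                 skip_reason = paste("error:", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, recs)
  if (!is.null(out_dir)) {
    num <- vapply(out, is.numeric, logical(1))
    out_fmt <- out
    out_fmt[num] <- lapply(out[num], signif, digits = 6)
    utils::write.csv(out_fmt, file.path(out_dir, "estimates.csv"), row.names = FALSE)
  }
  out
}

#' Simulate a cohort and write it to disk
#'
#' Writes one PNG + YAML calibration sidecar per case plus a `truth.csv`
#' ground-truth table.  Re-running with the same configuration (same master
#' seed) reproduces the truth table byte for byte.
#'
#' @param cfg A [cohort_config] or path to a YAML file with config fields.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of synthetic cases.
#' @export
cmd_simulate <- function(cfg = cohort_config(), out_dir) {
  if (is.character(cfg)) cfg <- read_cohort_config(cfg)
  stopifnot(inherits(cfg, "cohort_config"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) mrlap_error(sprintf("cannot create output directory: %s", out_dir),
                         "mrlap_config_error")
  }
  cases <- simulate_cohort(cfg)
  for (cs in cases) {
    write_spectrogram(cs$spectrogram, file.path(out_dir, paste0(cs$id, ".png")))
  }
  truth <- cohort_truth_table(cases)
  num <- vapply(truth, is.numeric, logical(1))
  truth[num] <- lapply(truth[num], signif, digits = 6)
  utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  invisible(cases)
}

#' Read a cohort configuration from YAML
#'
#' Recognised keys mirror the [cohort_config] arguments (noise fields flat:
#' `speckle_var`, `background_sd`, `soft_edge_px`, `base_intensity`).
#'
#' @param path YAML file path.
#' @return A [cohort_config].
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) {
    mrlap_error(sprintf("config file not found: %s", path), "mrlap_config_error")
  }
  y <- yaml::read_yaml(path)
  noise_keys <- c("speckle_var", "background_sd", "soft_edge_px", "base_intensity")
  noise_args <- y[intersect(names(y), noise_keys)]
  y <- y[setdiff(names(y), noise_keys)]
  if (!is.null(y$mix)) y$mix <- unlist(y$mix)
  args <- y[intersect(names(y), names(formals(cohort_config)))]
  if (length(noise_args)) args$noise <- do.call(render_noise, noise_args)
  do.call(cohort_config, args)
}

#' Compare an estimates table with a reference table
#'
#' Aligns the two tables on their shared `id` column, assembles the full
#' comparison report (paired tests, correlations, consistency table, subgroup
#' tests) via [cohort_report], and optionally writes it to a JSON file.
#'
#' @param estimates Data frame or CSV path with columns `id`, `lap_eq`
#'   (and optionally `lap_bp`, `v_peak`).
#' @param reference Data frame or CSV path with columns `id`, `lap_catheter`
#'   (and optionally `group`, `v_peak`, `p_radial_measured`).
#' @param out_file Optional JSON output path.
#' @return A `"cohort_report"` object.
#' @export
cmd_compare <- function(estimates, reference, out_file = NULL) {
  if (is.character(estimates)) estimates <- utils::read.csv(estimates)
  if (is.character(reference)) reference <- utils::read.csv(reference)
  rep <- cohort_report(reference, estimates)
  if (!is.null(out_file)) write_report(rep, out_file)
  rep
}
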