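# Assembly of the cohort method-comparison report.

#' Cohort method-comparison report
#'
#' Joins per-case estimates to the reference (catheter) readings and computes
#' the full comparison layout: paired t-tests and Pearson correlations of
#' each method against the catheter, the 10 % consistency grouping of the
#' sphygmomanometer method with its 2x2 disease-composition chi-square, and
#' rank-sum subgroup comparisons of the continuous covariates between the
#' consistent and inconsistent groups.
#'
#' @param reference Data frame with `id`, `lap_catheter`, and optionally
#'   `group` (disease group), `v_peak`, `p_radial_measured`.
#' @param estimates Data frame with `id`, `lap_eq`, optionally `lap_bp`.
#' @return An object of class `"cohort_report"` (a nested list, JSON-ready).
#' @export
cohort_report <- function(reference, estimates) {
  if (!is.data.frame(reference) || !is.data.frame(estimates) ||
      !"id" %in% names(reference) || !"id" %in% names(estimates)) {
    mrlap_error("both tables must be data frames with an `id` column",
                "mrlap_alignment_error")
  }
  ids <- intersect(reference$id, estimates$id)
  if (length(ids) == 0L) {
    mrlap_error("no overlapping case ids between estimates and reference",
                "mrlap_alignment_error")
  }
  ref <- reference[match(ids, reference$id), , drop = FALSE]
  est <- estimates[match(ids, estimates$id), , drop = FALSE]

  rep <- list(n_cases = length(ids))

  ok_eq <- is.finite(est$lap_eq) & is.finite(ref$lap_catheter)
  if (sum(ok_eq) >= 4) {
    rep$paired <- list(eq_vs_c = unclass(
      paired_ttest(est$lap_eq[ok_eq], ref$lap_catheter[ok_eq])))
    rep$correlation <- list(eq_vs_c = unclass(
      pearson_ci(est$lap_eq[ok_eq], ref$lap_catheter[ok_eq])))
  }

  has_bp <- "lap_bp" %in% names(est) && any(is.finite(est$lap_bp))
  if (has_bp) {
    ok_bp <- is.finite(est$lap_bp) & is.finite(ref$lap_catheter)
    if (sum(ok_bp) >= 4) {
      rep$paired$bp_vs_c <- unclass(
        paired_ttest(est$lap_bp[ok_bp], ref$lap_catheter[ok_bp]))
      rep$correlation$bp_vs_c <- unclass(
        pearson_ci(est$lap_bp[ok_bp], ref$lap_catheter[ok_bp]))

      stratum <- NULL
      if ("group" %in% names(ref)) {
        # the disease-composition stratum: eccentric-jet-prone prolapse vs rest
        stratum <- ifelse(ref$group[ok_bp] %in% c("MVP_A2P2", "MVP_P1P3"),
                          "MVP", "CABG_RHD")
      }
      cons <- consistency_grouping(est$lap_bp[ok_bp], ref$lap_catheter[ok_bp],
                                   stratum = stratum)
      rep$consistency <- list(rate = cons$rate,
                              n_consistent = sum(cons$consistent),
                              n_inconsistent = sum(!cons$consistent))
      if (!is.null(cons$table)) {
        rep$consistency$table <- as.data.frame.matrix(cons$table)
        if (all(dim(cons$table) == c(2L, 2L)) &&
            !any(rowSums(cons$table) == 0) && !any(colSums(cons$table) == 0)) {
          cs <- chi_square_2x2(cons$table, correct = TRUE)
          rep$consistency$chi_square <- list(statistic = cs$statistic, p = cs$p)
        }
      }
      # single-factor subgroup comparisons of continuous covariates
      sub <- list()
      for (var in intersect(c("p_radial_measured", "v_peak"), names(ref))) {
        a <- ref[[var]][ok_bp][cons$consistent]
        b <- ref[[var]][ok_bp][!cons$consistent]
        if (length(a) > 0 && length(b) > 0) {
          mw <- mann_whitney(a, b)
          sub[[var]] <- list(U = mw$U, p = mw$p,
                             median_consistent = stats::median(a),
                             median_inconsistent = stats::median(b))
        }
      }
      if (length(sub)) rep$subgroup <- sub
    }
  }
  structure(rep, class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort comparison report (%d cases)\n", x$n_cases))
  if (!is.null(x$paired)) {
    for (nm in names(x$paired)) {
      p <- x$paired[[nm]]
      cat(sprintf("  %s: mean diff %.3f, 95%% CI (%.3f, %.3f), t = %.3f, P = %.3g\n",
                  nm, p$mean_diff, p$ci[1], p$ci[2], p$t, p$p))
    }
  }
  if (!is.null(x$correlation)) {
    for (nm in names(x$correlation)) {
      r <- x$correlation[[nm]]
      cat(sprintf("  %s: r = %.3f (%.3f, %.3f), P = %.3g\n",
                  nm, r$r, r$ci[1], r$ci[2], r$p))
    }
  }
  if (!is.null(x$consistency)) {
    cat(sprintf("  consistency (<10%% of catheter): %d/%d (%.1f%%)\n",
                x$consistency$n_consistent,
                x$consistency$n_consistent + x$consistency$n_inconsistent,
                100 * x$consistency$rate))
    if (!is.null(x$consistency$chi_square)) {
      cat(sprintf("    disease composition chi-square = %.3f, P = %.3g\n",
                  x$consistency$chi_square$statistic, x$consistency$chi_square$p))
    }
  }
  if (!is.null(x$subgroup)) {
    for (nm in names(x$subgroup)) {
      s <- x$subgroup[[nm]]
      cat(sprintf("  subgroup %s: medians %.3g vs %.3g, U = %.1f, P = %.3g\n",
                  nm, s$median_consistent, s$median_inconsistent, s$U, s$p))
    }
  }
  invisible(x)
}

#' Write a cohort report to JSON
#'
#' @param rep A `"cohort_report"`.
#' @param path Output file path.
#' @export
write_report <- function(rep, path) {
  stopifnot(inherits(rep, "cohort_report"))
  jsonlite::write_json(unclass(rep), path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
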