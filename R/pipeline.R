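#' End-to-end synthetic cohort analysis
#'
#' Runs the complete perfusion analysis on a simulated cohort: renders every
#' acquisition (one cine clip per replicate), extracts the three ROI
#' time-intensity curves, fits the replenishment model with the R-squared
#' reliability gate, aggregates replicates per exam-region, and produces the
#' group-level outputs: the region-by-parameter comparison table, the
#' day-on-circuit strata tables, central-versus-peripheral contrasts,
#' cardiac correlations, the MCA pulsatility-index comparison, the
#' crossmatch test on the pooled (MFV, transit time) cloud, and per-group
#' parabolic regressions of transit time on MFV.
#'
#' Clips are rendered and processed one at a time, so memory stays modest
#' even for full cohorts.
#'
#' @param config a [cohort_config()].
#' @param crossmatch_mode `"exams"` pools every exam as one point (default);
#'   `"animals"` uses one per-animal median point.
#' @param out_dir optional directory; when given, every output table is also
#'   written as a CSV file.
#' @return List with `records` (replicate level), `exams` (aggregated),
#'   `truth`, `table1`, `strata`, `contrasts`, `correlations`, `doppler`,
#'   `pi_test`, `crossmatch`, `parabolas`, `n_excluded`, `n_missing`.
#' @export
run_cohort_analysis <- function(config,
                                crossmatch_mode = c("exams", "animals"),
                                out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  crossmatch_mode <- match.arg(crossmatch_mode)
  regions <- c("whole_brain", "central_thalamic", "peripheral_parenchyma")

  sim <- with_seed(config$seed, {
    truth <- draw_truth(config)
    rois <- cohort_rois(config$cine, config$roi_offset_mm)
    exams <- unique(truth[, c("animal_id", "group", "exam", "day")])
    rec_rows <- list()
    n_excluded <- 0L
    for (i in seq_len(nrow(exams))) {
      te <- truth[truth$animal_id == exams$animal_id[i] &
                    truth$exam == exams$exam[i], ]
      maps <- exam_tissue(config, te)
      for (rep_k in seq_len(config$replicate_count)) {
        cc <- config$cine
        cc$seed <- sample.int(.Machine$integer.max - 1L, 1L)
        clip <- simulate_cine(cc, maps$tissue,
                              id = sprintf("%s_ex%d_rep%d",
                                           exams$animal_id[i],
                                           exams$exam[i], rep_k))
        for (reg in regions) {
          curve <- extract_tic(clip, maps$rois[[reg]], replicate = rep_k)
          fit <- fit_reperfusion(curve)
          if (fit$excluded) {
            n_excluded <- n_excluded + 1L
            next
          }
          rec_rows[[length(rec_rows) + 1L]] <- derive_perfusion(
            fit, animal_id = exams$animal_id[i], group = exams$group[i],
            day_on_circuit = exams$day[i], region = reg,
            replicate = rep_k)
        }
      }
    }
    dop_rows <- list()
    med <- default_cardiac_medians()
    for (i in seq_len(nrow(exams))) {
      gm <- med[med$group == exams$group[i], ]
      # PSV/EDV jitter varies the pulsatility between exams; the envelope
      # itself stays clean (sample-level noise would inflate the raw
      # extrema and hence bias PI upward, where a real tracer smooths)
      jit <- exp(rnorm(2L, 0, config$dispersion / 2))
      tr <- simulate_doppler(gm$psv * jit[1L], gm$edv * jit[2L])
      dop_rows[[length(dop_rows) + 1L]] <- data.frame(
        animal_id = exams$animal_id[i], group = exams$group[i],
        day_on_circuit = exams$day[i], PI = compute_pi(tr),
        stringsAsFactors = FALSE)
    }
    list(truth = truth, exams = exams,
         records = do.call(rbind, rec_rows),
         doppler = do.call(rbind, dop_rows),
         n_excluded = n_excluded)
  })

  records <- sim$records
  # aggregate replicates per exam-region
  agg_rows <- list()
  n_missing <- 0L
  for (i in seq_len(nrow(sim$exams))) {
    for (reg in regions) {
      sub <- records[records$animal_id == sim$exams$animal_id[i] &
                       records$day_on_circuit == sim$exams$day[i] &
                       records$region == reg, , drop = FALSE]
      if (nrow(sub) == 0L) { n_missing <- n_missing + 1L; next }
      agg_rows[[length(agg_rows) + 1L]] <- aggregate_replicates(sub)
    }
  }
  exams_tab <- do.call(rbind, agg_rows)
  rownames(exams_tab) <- NULL

  table1 <- summarize_table1(exams_tab)
  strata <- summarize_strata(exams_tab)
  contrasts <- region_contrasts(exams_tab)

  cardiac <- simulate_cardiac_table(config)
  joined <- join_cardiac_perfusion(cardiac, exams_tab)
  correlations <- correlation_table(joined$joined)

  pi_test <- mann_whitney_u(
    sim$doppler$PI[sim$doppler$group == "hypoxic"],
    sim$doppler$PI[sim$doppler$group == "normoxic"],
    variable = "MCA_PI")

  wb <- exams_tab[exams_tab$region == "whole_brain", ]
  if (crossmatch_mode == "animals") {
    wb <- do.call(rbind, lapply(split(wb, wb$animal_id), function(d)
      data.frame(group = d$group[1L], MFV = median(d$MFV),
                 transit_time = median(d$transit_time))))
  }
  pts0 <- as.matrix(wb[wb$group == "hypoxic", c("MFV", "transit_time")])
  pts1 <- as.matrix(wb[wb$group == "normoxic", c("MFV", "transit_time")])
  xm <- crossmatch_test(pts0, pts1)
  # parabola fits need >= 4 points and 3 distinct velocities per group;
  # tiny cohorts may not provide them
  safe_parab <- function(p, g) tryCatch(
    fit_parabola(p[, "MFV"], p[, "transit_time"], group = g),
    ceusperf_invalid = function(e) NULL)
  parabolas <- list(hypoxic = safe_parab(pts0, "hypoxic"),
                    normoxic = safe_parab(pts1, "normoxic"))

  out <- list(records = records, exams = exams_tab, truth = sim$truth,
              table1 = table1, strata = strata, contrasts = contrasts,
              cardiac = cardiac, correlations = correlations,
              doppler = sim$doppler, pi_test = pi_test,
              crossmatch = xm, parabolas = parabolas,
              n_excluded = sim$n_excluded, n_missing = n_missing,
              n_cardiac_unmatched = joined$n_dropped)
  if (!is.null(out_dir)) write_analysis_csvs(out, out_dir)
  out
}

write_analysis_csvs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, name) if (!is.null(d))
    write.csv(d, file.path(out_dir, name), row.names = FALSE)
  w(result$records, "perfusion_replicates.csv")
  w(result$exams, "perfusion_exams.csv")
  w(result$truth, "truth.csv")
  w(result$table1, "table1_comparison.csv")
  w(result$strata, "strata_comparison.csv")
  w(result$contrasts$tests, "region_contrast_tests.csv")
  w(result$contrasts$contrasts, "region_contrasts.csv")
  w(result$cardiac, "cardiac_daily.csv")
  w(result$correlations, "cardiac_correlations.csv")
  w(result$doppler, "doppler_pi.csv")
  w(as.data.frame(result$pi_test), "pi_test.csv")
  xm <- result$crossmatch
  w(data.frame(n0 = xm$n0, n1 = xm$n1, a1 = xm$a1,
               expected_a1 = xm$expected_a1, p_value = xm$p_value,
               z = xm$z, p_approx = xm$p_approx),
    "crossmatch.csv")
  pb <- do.call(rbind, lapply(Filter(Negate(is.null), result$parabolas),
                              function(p)
    data.frame(group = p$group, c0 = p$coefficients[1L],
               c1 = p$coefficients[2L], c2 = p$coefficients[3L],
               r_squared = p$r_squared, n = p$n)))
  w(pb, "parabola_fits.csv")
  invisible(out_dir)
}
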