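#' Default group/region kinetic medians
#'
#' The generator's ground-truth medians for plateau amplitude `A` (au) and
#' replenishment rate `beta` (1/s), per group and region. They encode the
#' study's reported regional medians of MFV (au/s) and transit time (s)
#' through `beta = 1 / TT` and `A = MFV * TT`, so that `MFV = A * beta` and
#' `TT = 1 / beta` reproduce those medians exactly. (Reported medians of
#' MFV, TT and MBF cannot be jointly consistent for a single `(A, beta)` —
#' medians of nonlinear combinations do not compose — so MBF medians are
#' not additionally encoded.)
#'
#' @return `data.frame` with columns `group`, `region`, `MFV_median`,
#'   `TT_median`, `A`, `beta`.
#' @export
default_kinetic_medians <- function() {
  d <- data.frame(
    group = rep(c("hypoxic", "normoxic"), each = 3L),
    region = rep(c("whole_brain", "central_thalamic",
                   "peripheral_parenchyma"), 2L),
    MFV_median = c(0.78, 1.32, 0.59, 1.10, 1.47, 0.84),
    TT_median = c(0.99, 3.65, 3.84, 0.63, 3.17, 1.87),
    stringsAsFactors = FALSE)
  d$beta <- 1 / d$TT_median
  d$A <- d$MFV_median * d$TT_median
  d
}

#' Cohort simulation configuration
#'
#' Describes the synthetic study: group sizes, exams per animal and their
#' day range, the group/region kinetic medians, the log-scale dispersion of
#' animal and exam random effects, replicate acquisitions per exam, and the
#' cine geometry used when clips are rendered.
#'
#' @param n_hypoxic,n_normoxic animals per group (defaults 9 and 6).
#' @param exams_range integer range of CEUS exams per animal (1-3).
#' @param day_range inclusive integer day-on-circuit interval for exams
#'   (default 2-13; must lie within 1-21, the maximum circuit duration).
#' @param medians kinetic medians table as in [default_kinetic_medians()].
#' @param dispersion log-scale standard deviation of the animal-level
#'   multiplicative effects on `A` and `beta` (exam-level jitter uses half
#'   this value); `0` makes every animal's parameters equal the medians.
#' @param replicate_count acquisitions per exam (default 3, sequential
#'   triplicates).
#' @param cine a [cine_config()] for rendered clips.
#' @param roi_offset_mm row/column offset of the peripheral ROI center from
#'   the grid center, mm.
#' @param seed integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_hypoxic = 9L, n_normoxic = 6L,
                          exams_range = c(1L, 3L), day_range = c(2L, 13L),
                          medians = default_kinetic_medians(),
                          dispersion = 0.3, replicate_count = 3L,
                          cine = cine_config(), roi_offset_mm = c(0, 6),
                          seed = 1L) {
  check_scalar(n_hypoxic, "n_hypoxic", positive = TRUE, integerish = TRUE)
  check_scalar(n_normoxic, "n_normoxic", positive = TRUE, integerish = TRUE)
  check_scalar(dispersion, "dispersion", nonneg = TRUE)
  check_scalar(replicate_count, "replicate_count", positive = TRUE,
               integerish = TRUE)
  if (length(exams_range) != 2L || exams_range[1L] < 1L ||
      exams_range[2L] < exams_range[1L])
    stop_invalid("`exams_range` must be an increasing pair of counts >= 1")
  if (length(day_range) != 2L || day_range[1L] < 1L || day_range[2L] > 21L ||
      day_range[2L] < day_range[1L])
    stop_invalid("`day_range` must lie within [1, 21]")
  if (diff(day_range) + 1L < exams_range[2L])
    stop_invalid("day range too short for the maximum number of exams")
  if (any(medians$A <= 0) || any(medians$beta <= 0))
    stop_invalid("kinetic medians must be strictly positive")
  structure(list(n_hypoxic = as.integer(n_hypoxic),
                 n_normoxic = as.integer(n_normoxic),
                 exams_range = as.integer(exams_range),
                 day_range = as.integer(day_range),
                 medians = medians,
                 dispersion = dispersion,
                 replicate_count = as.integer(replicate_count),
                 cine = cine,
                 roi_offset_mm = roi_offset_mm,
                 seed = seed),
            class = "cohort_config")
}

# Draw the cohort's ground-truth table: one row per exam x region with the
# realized (A, beta) and derived MFV/TT/MBF. Animal effects are log-normal
# with median 1 (sdlog = dispersion), exam-level jitter sdlog = dispersion/2,
# independently for A and beta, shared across regions within an animal/exam.
draw_truth <- function(config) {
  groups <- c(rep("hypoxic", config$n_hypoxic),
              rep("normoxic", config$n_normoxic))
  ids <- sprintf("%s_%02d", ifelse(groups == "hypoxic", "H", "N"),
                 unlist(lapply(table(factor(groups,
                                            c("hypoxic", "normoxic"))),
                               seq_len)))
  days_avail <- config$day_range[1L]:config$day_range[2L]
  rows <- list()
  for (k in seq_along(ids)) {
    n_exams <- sample(config$exams_range[1L]:config$exams_range[2L], 1L)
    days <- sort(sample(days_avail, n_exams))
    eff_A <- exp(rnorm(1L, 0, config$dispersion))
    eff_B <- exp(rnorm(1L, 0, config$dispersion))
    med <- config$medians[config$medians$group == groups[k], ]
    for (ex in seq_len(n_exams)) {
      jit_A <- exp(rnorm(1L, 0, config$dispersion / 2))
      jit_B <- exp(rnorm(1L, 0, config$dispersion / 2))
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = ids[k], group = groups[k], exam = ex,
        day = days[ex], region = med$region,
        A = med$A * eff_A * jit_A,
        beta = med$beta * eff_B * jit_B,
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  truth$MFV <- truth$A * truth$beta
  truth$TT <- 1 / truth$beta
  truth$MBF <- truth$MFV^2 * truth$TT    # algebraically A^2 beta
  rownames(truth) <- NULL
  truth
}

# Standard ROI set for the synthetic cine geometry: 5-mm circles for the
# central/thalamic (grid center) and peripheral (offset) regions, and a
# whole-brain ellipse covering most of the grid.
cohort_rois <- function(cine, roi_offset_mm) {
  h <- cine$height_px; w <- cine$width_px; s <- cine$pixel_spacing_mm
  ctr <- c(h, w) * s / 2
  rows <- (seq_len(h) - 0.5) * s
  cols <- (seq_len(w) - 0.5) * s
  semi <- c(h, w) * s / 2 - 0.6 * s  # ellipse just inside the grid
  inside <- outer(((rows - ctr[1L]) / semi[1L])^2,
                  ((cols - ctr[2L]) / semi[2L])^2, `+`) <= 1
  list(
    whole_brain = roi_spec("whole_brain", mask = inside),
    central_thalamic = roi_spec("central_thalamic", center_mm = ctr,
                                diameter_mm = 5),
    peripheral_parenchyma = roi_spec("peripheral_parenchyma",
                                     center_mm = ctr + roi_offset_mm,
                                     diameter_mm = 5))
}

# Tissue map realizing one exam's regional truth on the cine grid:
# whole-brain parameters fill the brain ellipse, overwritten inside the
# central and peripheral circles by their own parameters; outside the brain
# the image is dark.
exam_tissue <- function(config, truth_exam) {
  cine <- config$cine
  rois <- cohort_rois(cine, config$roi_offset_mm)
  probe <- cine_clip(array(0, dim = c(cine$height_px, cine$width_px, 2L)),
                     frame_interval_s = 1, pixel_spacing_mm =
                       cine$pixel_spacing_mm)
  A <- matrix(0, cine$height_px, cine$width_px)
  B <- matrix(0, cine$height_px, cine$width_px)
  for (reg in c("whole_brain", "central_thalamic",
                "peripheral_parenchyma")) {
    mask <- rasterize_roi(rois[[reg]], probe)
    row <- truth_exam[truth_exam$region == reg, ]
    A[mask] <- row$A
    B[mask] <- row$beta
  }
  list(tissue = tissue_map(A, B), rois = rois)
}

#' Simulate a synthetic CEUS cohort
#'
#' Draws the cohort ground truth (per-exam regional kinetic parameters with
#' animal-level random effects centered on the configured medians) and,
#' optionally, renders every acquisition as a cine clip with its ROI set.
#'
#' @param config a [cohort_config()].
#' @param make_clips render cine clips (`TRUE`) or return the truth table
#'   only (`FALSE`, fast; used for distributional checks).
#' @return List with `truth` (one row per exam x region: `animal_id`,
#'   `group`, `exam`, `day`, `region`, `A`, `beta`, `MFV`, `TT`, `MBF`),
#'   `rois`, and — when `make_clips` — `clips`, a list with one entry per
#'   acquisition (`clip`, `animal_id`, `group`, `day`, `replicate`).
#' @export
simulate_cohort <- function(config, make_clips = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    truth <- draw_truth(config)
    rois <- cohort_rois(config$cine, config$roi_offset_mm)
    out <- list(truth = truth, rois = rois)
    if (make_clips) {
      exams <- unique(truth[, c("animal_id", "group", "exam", "day")])
      clips <- list()
      for (i in seq_len(nrow(exams))) {
        te <- truth[truth$animal_id == exams$animal_id[i] &
                      truth$exam == exams$exam[i], ]
        maps <- exam_tissue(config, te)
        for (rep_k in seq_len(config$replicate_count)) {
          cc <- config$cine
          cc$seed <- sample.int(.Machine$integer.max, 1L)
          clip <- simulate_cine(cc, maps$tissue,
                                id = sprintf("%s_ex%d_rep%d",
                                             exams$animal_id[i],
                                             exams$exam[i], rep_k))
          clips[[length(clips) + 1L]] <- list(
            clip = clip, animal_id = exams$animal_id[i],
            group = exams$group[i], day = exams$day[i],
            exam = exams$exam[i], replicate = rep_k)
        }
      }
      out$clips <- clips
    }
    out
  })
}

#' Simulate a Doppler velocity envelope
#'
#' Raised-cosine maximum-velocity envelope
#' `v(t) = edv + (psv - edv) * (1 + cos(2 pi f t)) / 2`, sampled over an
#' integer number of cardiac cycles; its time average is
#' `(psv + edv) / 2` in closed form. Optional multiplicative jitter models
#' envelope-tracing noise.
#'
#' @param psv,edv peak systolic and end-diastolic velocities, cm/s
#'   (`psv > edv >= 0`).
#' @param heart_rate_hz cardiac frequency, Hz.
#' @param n_cycles number of complete cycles.
#' @param sample_rate_hz envelope sampling rate, Hz.
#' @param noise_sigma log-scale sd of unit-median multiplicative jitter.
#' @param seed integer seed.
#' @return A [doppler_trace()].
#' @export
simulate_doppler <- function(psv, edv, heart_rate_hz = 2.5, n_cycles = 5L,
                             sample_rate_hz = 100, noise_sigma = 0,
                             seed = NULL) {
  check_scalar(psv, "psv", positive = TRUE)
  check_scalar(edv, "edv", nonneg = TRUE)
  if (psv <= edv) stop_invalid("`psv` must exceed `edv`")
  check_scalar(heart_rate_hz, "heart_rate_hz", positive = TRUE)
  check_scalar(n_cycles, "n_cycles", positive = TRUE, integerish = TRUE)
  check_scalar(sample_rate_hz, "sample_rate_hz", positive = TRUE)
  check_scalar(noise_sigma, "noise_sigma", nonneg = TRUE)
  n <- round(n_cycles * sample_rate_hz / heart_rate_hz)
  t <- (seq_len(n) - 1L) / sample_rate_hz
  v <- edv + (psv - edv) * (1 + cos(2 * pi * heart_rate_hz * t)) / 2
  if (noise_sigma > 0)
    v <- with_seed(seed, v * exp(rnorm(n, 0, noise_sigma)))
  doppler_trace(t, v, n_cycles = n_cycles, heart_rate_hz = heart_rate_hz)
}

#' Default cardiac output and Doppler generator medians
#'
#' Group medians for the daily cardiac table and the MCA Doppler envelopes.
#' Circuit flow (221 vs 278 mL/kg/min) and shunt fraction (0.29 vs 0.35)
#' encode the reported group medians; combined output follows as
#' `circuit_flow / shunt_fraction` split between the ventricles at a
#' fetal LVCO:RVCO of about 0.8. Doppler PSV/EDV are chosen so the
#' raised-cosine pulsatility index reproduces the reported group medians
#' (0.65 hypoxic, 0.78 normoxic).
#'
#' @return `data.frame` keyed by `group`.
#' @export
default_cardiac_medians <- function() {
  data.frame(
    group = c("hypoxic", "normoxic"),
    LVCO = c(345, 353),
    RVCO = c(417, 441),
    circuit_flow = c(221, 278),
    psv = c(40, 40),
    edv = c(40 * (2 - 0.65) / (2 + 0.65), 40 * (2 - 0.78) / (2 + 0.78)),
    stringsAsFactors = FALSE)
}

#' Simulate the daily cardiac table
#'
#' One row per animal-day over the configured day range, with LVCO, RVCO
#' and circuit flow drawn log-normally around the group medians (animal
#' effect sdlog = dispersion, day jitter sdlog = dispersion / 2) and the
#' derived CCO, LVCO:RVCO ratio and shunt fraction from [derive_cardiac()].
#'
#' @param config a [cohort_config()].
#' @param medians per-group medians as in [default_cardiac_medians()].
#' @return `data.frame` with one row per animal-day.
#' @export
simulate_cardiac_table <- function(config,
                                   medians = default_cardiac_medians()) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- if (is.null(config$seed)) NULL else config$seed + 1000L
  with_seed(seed, {
    groups <- c(rep("hypoxic", config$n_hypoxic),
                rep("normoxic", config$n_normoxic))
    ids <- sprintf("%s_%02d", ifelse(groups == "hypoxic", "H", "N"),
                   unlist(lapply(table(factor(groups,
                                              c("hypoxic", "normoxic"))),
                                 seq_len)))
    n_days <- config$day_range[2L]
    med <- medians[match(groups, medians$group), ]
    n <- length(ids) * n_days
    animal <- rep(seq_along(ids), each = n_days)
    eff <- matrix(exp(rnorm(3L * length(ids), 0, config$dispersion)),
                  ncol = 3L)                       # LVCO, RVCO, circuit
    jit <- matrix(exp(rnorm(3L * n, 0, config$dispersion / 2)), ncol = 3L)
    LVCO <- med$LVCO[animal] * eff[animal, 1L] * jit[, 1L]
    RVCO <- med$RVCO[animal] * eff[animal, 2L] * jit[, 2L]
    circuit <- med$circuit_flow[animal] * eff[animal, 3L] * jit[, 3L]
    CCO <- LVCO + RVCO
    data.frame(animal_id = ids[animal], day = rep(seq_len(n_days),
                                                  length(ids)),
               LVCO = LVCO, RVCO = RVCO, CCO = CCO,
               circuit_flow = circuit,
               lv_rv_ratio = LVCO / RVCO,
               shunt_fraction = circuit / CCO,
               group = groups[animal],
               stringsAsFactors = FALSE)
  })
}
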