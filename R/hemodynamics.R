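#' Doppler velocity envelope trace
#'
#' @param times_s sample times, seconds.
#' @param envelope_velocity maximum-velocity envelope samples, cm/s.
#' @param n_cycles integer number of complete cardiac cycles spanned.
#' @param heart_rate_hz cardiac frequency, Hz.
#' @return Object of class `doppler_trace` with the samples plus `PSV`
#'   (peak systolic), `EDV` (end-diastolic = minimum) and `TAMV`
#'   (time-averaged envelope) velocities.
#' @export
doppler_trace <- function(times_s, envelope_velocity, n_cycles,
                          heart_rate_hz) {
  if (length(times_s) != length(envelope_velocity))
    stop_invalid("times and envelope must have equal length")
  if (anyNA(envelope_velocity) || min(envelope_velocity) < 0)
    stop_invalid("envelope velocities must be non-negative")
  check_scalar(n_cycles, "n_cycles", positive = TRUE, integerish = TRUE)
  check_scalar(heart_rate_hz, "heart_rate_hz", positive = TRUE)
  structure(list(times_s = as.numeric(times_s),
                 envelope_velocity = as.numeric(envelope_velocity),
                 n_cycles = as.integer(n_cycles),
                 heart_rate_hz = heart_rate_hz,
                 PSV = max(envelope_velocity),
                 EDV = min(envelope_velocity),
                 TAMV = mean(envelope_velocity)),
            class = "doppler_trace")
}

#' Doppler pulsatility index
#'
#' `PI = (PSV - EDV) / TAMV` computed over the trace's integer number of
#' cardiac cycles. Invariant to velocity scaling and time shifts; tends to
#' zero as the envelope flattens.
#'
#' @param trace a [doppler_trace()] spanning at least one full cycle.
#' @return Single numeric PI (dimensionless).
#' @export
compute_pi <- function(trace) {
  stopifnot(inherits(trace, "doppler_trace"))
  if (trace$TAMV <= 0)
    stop(errorCondition("pulsatility index undefined: zero time-averaged velocity",
                        class = c("ceusperf_undefined", "error")))
  (trace$PSV - trace$EDV) / trace$TAMV
}

#' Derive cardiac output summary variables
#'
#' Combined cardiac output is the sum of the ventricular outputs,
#' `lv_rv_ratio = LVCO / RVCO`, and the shunt fraction is the proportion of
#' the combined output diverted to the oxygenator circuit,
#' `circuit_flow / CCO` (values above 1 are reported as-is with a warning).
#'
#' @param LVCO,RVCO left/right ventricular output, mL/kg/min (`RVCO > 0`).
#' @param circuit_flow oxygenator circuit flow, mL/kg/min, or `NA`.
#' @param animal_id,day optional labels.
#' @return One-row `data.frame`: inputs plus `CCO`, `lv_rv_ratio`,
#'   `shunt_fraction`.
#' @export
derive_cardiac <- function(LVCO, RVCO, circuit_flow = NA_real_,
                           animal_id = NA_character_, day = NA_integer_) {
  check_scalar(LVCO, "LVCO", nonneg = TRUE)
  check_scalar(RVCO, "RVCO", nonneg = TRUE)
  if (RVCO <= 0)
    stop(errorCondition("LVCO:RVCO undefined when RVCO = 0",
                        class = c("ceusperf_undefined", "error")))
  CCO <- LVCO + RVCO
  shunt <- if (is.na(circuit_flow)) NA_real_ else circuit_flow / CCO
  if (!is.na(shunt) && shunt > 1)
    warning("shunt fraction exceeds 1 (circuit flow above combined output)")
  data.frame(animal_id = as.character(animal_id), day = as.integer(day),
             LVCO = LVCO, RVCO = RVCO, CCO = CCO,
             circuit_flow = circuit_flow,
             lv_rv_ratio = LVCO / RVCO,
             shunt_fraction = shunt,
             stringsAsFactors = FALSE)
}

#' Pair CEUS exams with same-day cardiac records
#'
#' Joins each perfusion exam row to the cardiac record of the same animal
#' and day; exams without a same-day cardiac row are dropped and counted.
#'
#' @param cardiac `data.frame` with `animal_id`, `day` and cardiac columns.
#' @param perfusion exam-level perfusion `data.frame` with `animal_id`,
#'   `day_on_circuit`.
#' @return List with `joined` (one row per matched exam-region) and
#'   `n_dropped` (exam-region rows without a cardiac match).
#' @export
join_cardiac_perfusion <- function(cardiac, perfusion) {
  if (nrow(cardiac) == 0L || nrow(perfusion) == 0L)
    stop_invalid("empty input table")
  ck <- paste(cardiac$animal_id, cardiac$day, sep = "::")
  pk <- paste(perfusion$animal_id, perfusion$day_on_circuit, sep = "::")
  if (anyDuplicated(ck))
    stop_invalid("multiple cardiac rows for one animal-day")
  hit <- match(pk, ck)
  if (all(is.na(hit)))
    stop_invalid("no overlapping animal-day keys between the tables")
  keep <- !is.na(hit)
  joined <- cbind(perfusion[keep, , drop = FALSE],
                  cardiac[hit[keep],
                          setdiff(names(cardiac), c("animal_id", "day")),
                          drop = FALSE])
  rownames(joined) <- NULL
  list(joined = joined, n_dropped = sum(!keep))
}
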