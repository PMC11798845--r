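#' Stratify an exam by days on circuit
#'
#' Exams at 4 or fewer days on the support circuit are "early", those at 9
#' or more days "late", and days 5-8 "intermediate".
#'
#' @param day_on_circuit integer vector of days (>= 1).
#' @return Character vector in `{"early", "intermediate", "late"}`.
#' @export
stratify <- function(day_on_circuit) {
  if (!is.numeric(day_on_circuit) || anyNA(day_on_circuit) ||
      any(day_on_circuit < 1))
    stop_invalid("days on circuit must be positive integers")
  ifelse(day_on_circuit <= 4, "early",
         ifelse(day_on_circuit >= 9, "late", "intermediate"))
}

#' Mann-Whitney U test with continuity correction
#'
#' Computes the U statistic from midranks and a two-sided p value from the
#' normal approximation with tie-corrected variance and a 0.5 continuity
#' correction. For small tie-free samples (`n1 + n2 <= 10`) the exact null
#' distribution replaces the approximation.
#'
#' @param x,y numeric samples (group 1 and group 2).
#' @param variable,region,stratum optional labels carried into the result.
#' @return One-row `data.frame` of class `group_test`: sample sizes, group
#'   medians and IQRs, `U` (for `x`), `z`, `p_raw`, and the method used.
#' @export
mann_whitney_u <- function(x, y, variable = NA_character_,
                           region = NA_character_, stratum = "all") {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop_invalid("both samples must be nonempty")
  N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  tie_counts <- table(r)
  has_ties <- any(tie_counts > 1)
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 *
    ((N + 1) - sum(tie_counts^3 - tie_counts) / (N * (N - 1)))
  num <- U - mu
  num_cc <- sign(num) * max(abs(num) - 0.5, 0)
  z <- if (sigma2 > 0) num_cc / sqrt(sigma2) else 0
  if (!has_ties && N <= 10) {
    method <- "exact"
    p <- if (U == mu) 1
         else if (U < mu) 2 * pwilcox(U, n1, n2)
         else 2 * (1 - pwilcox(U - 1, n1, n2))
  } else {
    method <- "normal_approx"
    p <- 2 * pnorm(-abs(z))
  }
  p <- min(max(p, 0), 1)
  structure(
    data.frame(variable = variable, region = region, stratum = stratum,
               n1 = n1, n2 = n2,
               median1 = median(x), iqr1 = iqr(x),
               median2 = median(y), iqr2 = iqr(y),
               U = U, z = z, p_raw = p, method = method,
               stringsAsFactors = FALSE),
    class = c("group_test", "data.frame"))
}

# type-7 (linear interpolation) interquartile range
iqr <- function(x) {
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  q[2L] - q[1L]
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p values: the sorted raw values are scaled by `m / i`,
#' made monotone by a cumulative minimum from the largest, capped at 1, and
#' returned in the original order. Values outside `[0, 1]` are rejected.
#'
#' @param p_values numeric vector of raw p values in `[0, 1]`.
#' @return Adjusted p values, same order and length; never below the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1))
    stop_invalid("p values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Spearman rank correlation with t-approximation p value
#'
#' `rho` is the Pearson correlation of midranks; the two-sided p value uses
#' the t distribution with `n - 2` degrees of freedom. A constant input
#' leaves `rho` undefined (`NA` with `defined = FALSE`), not zero.
#'
#' @param x,y paired numeric samples, `n >= 3`.
#' @param cardiac_variable,perfusion_variable,region,group optional labels.
#' @return One-row `data.frame` of class `correlation_result` with `rho`,
#'   `p_raw`, `n`, `defined`.
#' @export
spearman_rho <- function(x, y, cardiac_variable = NA_character_,
                         perfusion_variable = NA_character_,
                         region = NA_character_, group = NA_character_) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop_invalid("Spearman correlation needs n >= 3 pairs")
  rx <- rank(x); ry <- rank(y)
  defined <- sd(rx) > 0 && sd(ry) > 0
  if (defined) {
    rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
    }
  } else {
    rho <- NA_real_; p <- NA_real_
  }
  structure(
    data.frame(cardiac_variable = cardiac_variable,
               perfusion_variable = perfusion_variable,
               region = region, group = group,
               n = n, rho = rho, p_raw = p, defined = defined,
               stringsAsFactors = FALSE),
    class = c("correlation_result", "data.frame"))
}

#' Group comparison table of perfusion parameters by region
#'
#' For each region and parameter (MFV, transit time, MBF) reports the
#' hypoxic and normoxic medians with interquartile ranges and the
#' Mann-Whitney p value, Benjamini-Hochberg adjusted across the table's
#' 3 x 3 family.
#'
#' @param records exam-level perfusion `data.frame` with columns `group`,
#'   `region`, `MFV`, `transit_time`, `MBF` (e.g. from
#'   [aggregate_replicates()] rows bound together).
#' @param params parameters to tabulate.
#' @return `data.frame` with one row per region x parameter: group medians,
#'   IQRs, `p_raw`, `p_adjusted`, `significant` (adjusted p <= 0.05).
#' @export
summarize_table1 <- function(records,
                             params = c("MFV", "transit_time", "MBF")) {
  regions <- c("whole_brain", "central_thalamic", "peripheral_parenchyma")
  regions <- regions[regions %in% unique(records$region)]
  rows <- list()
  for (param in params) {
    for (reg in regions) {
      hx <- records[[param]][records$group == "hypoxic" &
                               records$region == reg]
      nx <- records[[param]][records$group == "normoxic" &
                               records$region == reg]
      hx <- hx[!is.na(hx)]; nx <- nx[!is.na(nx)]
      if (length(hx) == 0L || length(nx) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = param, region = reg, stratum = "all",
          n1 = length(hx), n2 = length(nx),
          median1 = NA_real_, iqr1 = NA_real_,
          median2 = NA_real_, iqr2 = NA_real_,
          U = NA_real_, z = NA_real_, p_raw = NA_real_,
          method = "missing", stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <-
          mann_whitney_u(hx, nx, variable = param, region = reg)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  ok <- !is.na(out$p_raw)
  out$p_adjusted[ok] <- bh_adjust(out$p_raw[ok])
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted <= 0.05
  rownames(out) <- NULL
  out
}

#' Stratified group comparison tables
#'
#' Repeats [summarize_table1()] within each day-on-circuit stratum, with the
#' Benjamini-Hochberg family restricted to each stratum's own tests.
#'
#' @inheritParams summarize_table1
#' @return `data.frame` stacking the per-stratum tables, with a `stratum`
#'   column in `{"early", "intermediate", "late"}`.
#' @export
summarize_strata <- function(records,
                             params = c("MFV", "transit_time", "MBF")) {
  out <- list()
  for (st in c("early", "intermediate", "late")) {
    sub <- records[records$stratum == st, , drop = FALSE]
    if (nrow(sub) == 0L) next
    tab <- summarize_table1(sub, params = params)
    tab$stratum <- st
    out[[st]] <- tab
  }
  if (length(out) == 0L) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Central-versus-peripheral regional contrasts
#'
#' For every exam with both a central/thalamic and a peripheral-parenchyma
#' record, computes the absolute difference (central - peripheral) and the
#' ratio (central / peripheral) of each perfusion parameter, then compares
#' each contrast between groups with Mann-Whitney U tests,
#' Benjamini-Hochberg adjusted within this 6-test family.
#'
#' @inheritParams summarize_table1
#' @return List with `contrasts` (per-exam values) and `tests` (group
#'   comparisons); exams missing one region are skipped and counted in
#'   `n_skipped`.
#' @export
region_contrasts <- function(records,
                             params = c("MFV", "transit_time", "MBF")) {
  cen <- records[records$region == "central_thalamic", , drop = FALSE]
  per <- records[records$region == "peripheral_parenchyma", , drop = FALSE]
  key <- function(d) paste(d$animal_id, d$day_on_circuit, sep = "::")
  cen$key <- key(cen); per$key <- key(per)
  shared <- intersect(cen$key, per$key)
  n_skipped <- length(union(cen$key, per$key)) - length(shared)
  if (length(shared) == 0L) stop_invalid("no paired central/peripheral exams")
  cen <- cen[match(shared, cen$key), ]
  per <- per[match(shared, per$key), ]
  contrasts <- list()
  for (param in params) {
    ratio <- ifelse(per[[param]] > 0, cen[[param]] / per[[param]], NA_real_)
    contrasts[[param]] <- data.frame(
      animal_id = cen$animal_id, group = cen$group,
      day_on_circuit = cen$day_on_circuit, stratum = cen$stratum,
      parameter = param,
      central_value = cen[[param]], peripheral_value = per[[param]],
      absolute_difference = cen[[param]] - per[[param]],
      ratio = ratio, stringsAsFactors = FALSE)
  }
  contrasts <- do.call(rbind, contrasts)
  rownames(contrasts) <- NULL
  tests <- list()
  for (param in params) {
    sub <- contrasts[contrasts$parameter == param, ]
    for (what in c("absolute_difference", "ratio")) {
      v <- sub[[what]]
      tests[[paste(param, what)]] <- mann_whitney_u(
        v[sub$group == "hypoxic"], v[sub$group == "normoxic"],
        variable = paste0(param, "_", what))
    }
  }
  tests <- do.call(rbind, tests)
  tests$p_adjusted <- bh_adjust(tests$p_raw)
  tests$significant <- tests$p_adjusted <= 0.05
  rownames(tests) <- NULL
  list(contrasts = contrasts, tests = tests, n_skipped = n_skipped)
}

#' Cardiac-perfusion correlation table
#'
#' Spearman correlations of each cardiac variable against each perfusion
#' parameter, per group and region, Benjamini-Hochberg adjusted across the
#' whole table family.
#'
#' @param joined paired exam-level table from [join_cardiac_perfusion()].
#' @param cardiac_vars,perfusion_vars columns to correlate.
#' @return `data.frame` with `rho`, `p_raw`, `p_adjusted` per combination;
#'   combinations with fewer than 3 pairs or undefined rank variance are
#'   reported with `NA`.
#' @export
correlation_table <- function(joined,
                              cardiac_vars = c("CCO", "LVCO", "RVCO",
                                               "lv_rv_ratio"),
                              perfusion_vars = c("MFV", "transit_time",
                                                 "MBF")) {
  rows <- list()
  for (grp in unique(joined$group)) {
    for (reg in unique(joined$region)) {
      sub <- joined[joined$group == grp & joined$region == reg, ]
      for (cv in cardiac_vars) {
        for (pv in perfusion_vars) {
          ok <- !(is.na(sub[[cv]]) | is.na(sub[[pv]]))
          if (sum(ok) < 3L) {
            rows[[length(rows) + 1L]] <- data.frame(
              cardiac_variable = cv, perfusion_variable = pv,
              region = reg, group = grp, n = sum(ok),
              rho = NA_real_, p_raw = NA_real_, defined = FALSE,
              stringsAsFactors = FALSE)
          } else {
            rows[[length(rows) + 1L]] <- spearman_rho(
              sub[[cv]][ok], sub[[pv]][ok],
              cardiac_variable = cv, perfusion_variable = pv,
              region = reg, group = grp)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  ok <- !is.na(out$p_raw)
  out$p_adjusted[ok] <- bh_adjust(out$p_raw[ok])
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted <= 0.05
  rownames(out) <- NULL
  out
}
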