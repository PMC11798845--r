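test_that("day-on-circuit strata split at 4 and 9 days", {
  expect_identical(stratify(c(1, 4, 5, 8, 9, 13)),
                   c("early", "early", "intermediate", "intermediate",
                     "late", "late"))
  expect_error(stratify(0), class = "ceusperf_invalid")
})

test_that("Mann-Whitney U handles the exact, tied and approximate branches", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_identical(res$U, 0)
  expect_identical(res$method, "exact")
  expect_equal(res$p_raw, 1 / 3, tolerance = 1e-12)
  # identical tied samples: U at its null mean, p ~ 1
  res2 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res2$U, 4.5)
  expect_gt(res2$p_raw, 0.99)
  # the exact branch equals the label-enumeration oracle on tie-free
  # small samples
  set.seed(77)
  for (rep_i in 1:20) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- rnorm(n1); y <- rnorm(n2, 0.5)
    p_enum <- enum_mw_p(x, y)
    res <- mann_whitney_u(x, y)
    expect_identical(res$method, "exact")
    expect_equal(res$p_raw, p_enum, tolerance = 1e-12)
  }
  # near-balanced samples of 9-10: continuity-corrected normal approximation
  # tracks the exact p within 0.03, exhaustively over all U
  for (n1 in 3:5) for (n2 in 3:5) {
    if (n1 + n2 < 9) next
    mu <- n1 * n2 / 2
    sig <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
    for (U in 0:(n1 * n2)) {
      ex <- if (U == mu) 1 else if (U < mu) 2 * pwilcox(U, n1, n2) else
        2 * (1 - pwilcox(U - 1, n1, n2))
      num <- sign(U - mu) * max(abs(U - mu) - 0.5, 0)
      ap <- min(2 * pnorm(-abs(num / sig)), 1)
      expect_lt(abs(ap - min(ex, 1)), 0.03)
    }
  }
  expect_error(mann_whitney_u(numeric(0), 1), class = "ceusperf_invalid")
})

test_that("U statistics of the two groups always sum to n1 * n2", {
  set.seed(11)
  for (rep_i in 1:30) {
    n1 <- sample(2:12, 1); n2 <- sample(2:12, 1)
    x <- round(rnorm(n1), sample(0:2, 1))  # induce occasional ties
    y <- round(rnorm(n2), 1)
    u1 <- mann_whitney_u(x, y)$U
    u2 <- mann_whitney_u(y, x)$U
    expect_equal(u1 + u2, n1 * n2, tolerance = 1e-12)
    expect_gte(u1, 0); expect_lte(u1, n1 * n2)
  }
})

test_that("Mann-Whitney keeps nominal size on null data", {
  set.seed(101)
  rej <- mean(vapply(seq_len(500), function(i)
    mann_whitney_u(rnorm(9), rnorm(6))$p_raw <= 0.05, NA))
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.09)
})

test_that("Benjamini-Hochberg step-up matches its closed forms", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(c(0.05, 0.5)), c(0.10, 0.5))
  # order invariance and the never-below-raw guarantee
  set.seed(4)
  p <- runif(12)^2
  perm <- sample(12)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_true(all(bh_adjust(p) >= p))
  expect_true(all(bh_adjust(p) <= 1))
  expect_error(bh_adjust(c(0.1, 1.2)), class = "ceusperf_invalid")
})

test_that("Spearman rho is midrank-Pearson with a t-approximation", {
  x <- c(1, 3, 4, 7, 9)
  expect_equal(spearman_rho(x, 2 * x + 1)$rho, 1)
  expect_equal(spearman_rho(x, -x)$rho, -1)
  # tied data: agree with the direct rank formula and with cor()
  set.seed(6)
  for (rep_i in 1:10) {
    a <- sample(1:4, 8, replace = TRUE)
    b <- rnorm(8)
    got <- spearman_rho(a, b)
    expect_equal(got$rho, cor(rank(a), rank(b)), tolerance = 1e-12)
    expect_equal(got$rho, cor(a, b, method = "spearman"), tolerance = 1e-12)
  }
  # constant input: undefined, flagged, not zero
  res <- spearman_rho(rep(2, 5), rnorm(5))
  expect_false(res$defined)
  expect_true(is.na(res$rho))
  expect_error(spearman_rho(1:2, 1:2), class = "ceusperf_invalid")
})

test_that("group summary tables report median, IQR and adjusted p", {
  expect_equal(ceusperf:::iqr(c(1, 2, 3, 4)), 1.5)   # type-7 quantiles
  mk <- function(group, region, v) data.frame(
    animal_id = "x", group = group, day_on_circuit = 5,
    stratum = "intermediate", region = region, MFV = v,
    transit_time = v + 1, MBF = v^2, stringsAsFactors = FALSE)
  same <- rbind(mk("hypoxic", "whole_brain", c(1, 2, 3, 4)),
                mk("normoxic", "whole_brain", c(1, 2, 3, 4)))
  tab <- summarize_table1(same)
  expect_identical(nrow(tab), 3L)   # one region present, three parameters
  expect_equal(tab$median1[tab$variable == "MFV"], 2.5)
  expect_equal(tab$iqr1[tab$variable == "MFV"], 1.5)
  expect_true(all(tab$p_adjusted > 0.9))
  expect_false(any(tab$significant))
})

test_that("regional contrasts pair exams and test both difference and ratio", {
  mk <- function(animal, group, day, region, mfv) data.frame(
    animal_id = animal, group = group, day_on_circuit = day,
    stratum = stratify(day), region = region, MFV = mfv,
    transit_time = 1 / mfv, MBF = mfv, stringsAsFactors = FALSE)
  recs <- rbind(
    mk("h1", "hypoxic", 3, "central_thalamic", 2),
    mk("h1", "hypoxic", 3, "peripheral_parenchyma", 1),
    mk("h2", "hypoxic", 5, "central_thalamic", 2.4),
    mk("h2", "hypoxic", 5, "peripheral_parenchyma", 1.2),
    mk("n1", "normoxic", 4, "central_thalamic", 3),
    mk("n1", "normoxic", 4, "peripheral_parenchyma", 3),
    mk("n2", "normoxic", 6, "central_thalamic", 2.2),
    mk("n2", "normoxic", 6, "peripheral_parenchyma", 2.2),
    mk("n3", "normoxic", 9, "central_thalamic", 1.5))  # unpaired: dropped
  rc <- region_contrasts(recs)
  expect_identical(rc$n_skipped, 1L)
  expect_identical(nrow(rc$contrasts), 4L * 3L)
  mfv <- rc$contrasts[rc$contrasts$parameter == "MFV", ]
  expect_equal(mfv$absolute_difference[mfv$animal_id == "h1"], 1)
  expect_equal(mfv$ratio[mfv$animal_id == "h1"], 2)
  expect_equal(mfv$absolute_difference[mfv$animal_id == "n1"], 0)
  expect_equal(mfv$ratio[mfv$animal_id == "n1"], 1)
  expect_identical(nrow(rc$tests), 6L)  # 3 parameters x {difference, ratio}
  expect_true(all(rc$tests$p_adjusted >= rc$tests$p_raw))
})

test_that("ratio contrasts detect scale differences that differences miss", {
  # both groups share central >> peripheral structure; the hypoxic group is
  # globally scaled down, so ratios are equal-powered but differences mix
  # scale and contrast. With a pure ratio effect the ratio test must flag
  # the difference between groups at least as strongly.
  set.seed(30)
  mk_grp <- function(group, n, ratio, scale) {
    per <- exp(rnorm(n, 0, 0.6)) * scale
    do.call(rbind, lapply(seq_len(n), function(i) data.frame(
      animal_id = paste0(group, i), group = group,
      day_on_circuit = 5, stratum = "intermediate",
      region = c("central_thalamic", "peripheral_parenchyma"),
      MFV = c(per[i] * ratio * exp(rnorm(1, 0, 0.05)), per[i]),
      transit_time = 1, MBF = 1, stringsAsFactors = FALSE)))
  }
  recs <- rbind(mk_grp("hypoxic", 9, ratio = 1.4, scale = 1),
                mk_grp("normoxic", 6, ratio = 2.4, scale = 1))
  rc <- region_contrasts(recs, params = "MFV")
  p_ratio <- rc$tests$p_raw[rc$tests$variable == "MFV_ratio"]
  p_diff <- rc$tests$p_raw[rc$tests$variable == "MFV_absolute_difference"]
  expect_lt(p_ratio, 0.05)
  expect_lte(p_ratio, p_diff)
})

test_that("cohort medians simulated at the configured values are recovered", {
  # Sampling error of a group sample median with log-normal animal effects:
  # MFV carries sdlog sqrt(2) * 0.3 = 0.42 (effects on A and beta multiply),
  # TT sdlog 0.3. With 6-9 animals the median's log-scale SE is roughly
  # 1.25 * sdlog / sqrt(6) = 0.22 (MFV) / 0.15 (TT), so a single cohort
  # lands within 25% of the configured value with probability ~0.70 (MFV) /
  # ~0.86 (TT); the across-seed median of medians is centered.
  meds <- vapply(1:200, function(s) {
    tr <- simulate_cohort(cohort_config(dispersion = 0.3, seed = s),
                          make_clips = FALSE)$truth
    wb <- tr[tr$region == "whole_brain", ]
    c(mfv_h = median(wb$MFV[wb$group == "hypoxic"]),
      mfv_n = median(wb$MFV[wb$group == "normoxic"]),
      tt_h = median(wb$TT[wb$group == "hypoxic"]),
      tt_n = median(wb$TT[wb$group == "normoxic"]))
  }, c(mfv_h = 0, mfv_n = 0, tt_h = 0, tt_n = 0))
  cfg <- c(0.78, 1.10, 0.99, 0.63)
  for (k in 1:4) {
    expect_equal(median(meds[k, ]), cfg[k], tolerance = 0.10)
    frac25 <- mean(abs(meds[k, ] - cfg[k]) / cfg[k] < 0.25)
    expect_gte(frac25, if (k <= 2) 0.60 else 0.75)
  }
  # and the summary table reports exactly those sample medians
  tr <- simulate_cohort(cohort_config(dispersion = 0.3, seed = 1),
                        make_clips = FALSE)$truth
  recs <- data.frame(animal_id = tr$animal_id, group = tr$group,
                     day_on_circuit = tr$day, stratum = stratify(tr$day),
                     region = tr$region, MFV = tr$MFV,
                     transit_time = tr$TT, MBF = tr$MBF,
                     stringsAsFactors = FALSE)
  tab <- summarize_table1(recs)
  wb <- tr[tr$region == "whole_brain", ]
  expect_equal(tab$median1[tab$variable == "MFV" &
                             tab$region == "whole_brain"],
               median(wb$MFV[wb$group == "hypoxic"]))
})
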