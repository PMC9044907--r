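test_that("no marker change gives exactly zero RRR", {
  fit <- shared_fit("kidney")
  tr <- shared_trial()
  frozen <- tr
  for (nm in fit$markers$name) {
    frozen[[paste0(nm, "_fu")]] <- frozen[[paste0(nm, "_bl")]]
  }
  expect_identical(pre_rrr(fit, frozen)$rrr_percent, 0)
  expect_identical(single_marker_rrr(fit, frozen, "uacr")$rrr_percent, 0)
  expect_identical(pre_rrr(fit, frozen, form = "ratio")$rrr_percent, 0)
})

test_that("two-patient worked example matches independent arithmetic", {
  # placebo lp 0 -> 0; treatment lp 0 -> -ln 2; H0 = 0.1
  fit <- manual_fit(beta = log(2), H0 = 0.1)
  trial <- two_patient_trial(shift = -1)
  res <- pre_rrr(fit, trial, horizon = 5)
  # independent per-patient arithmetic (no package code)
  r_p_bl <- 1 - exp(-0.1); r_p_fu <- 1 - exp(-0.1)
  r_t_bl <- 1 - exp(-0.1); r_t_fu <- 1 - exp(-0.1 * 0.5)
  expected <- -100 * ((r_t_fu - r_t_bl) / r_t_bl - (r_p_fu - r_p_bl) / r_p_bl)
  expect_equal(res$rrr_percent, expected, tolerance = 1e-12)
  expect_equal(res$rrr_percent, 48.750260351579, tolerance = 1e-10)
})

test_that("identical changes applied to both arms cancel exactly", {
  fit <- manual_fit(beta = c(0.3, -0.2), H0 = 0.2, names_ = c("x1", "x2"))
  set.seed(80)
  base <- tibble::tibble(x1_bl = rnorm(50), x2_bl = rnorm(50),
                         x1_fu = NA_real_, x2_fu = NA_real_)
  # identical patients in both arms, identical per-patient changes
  tr <- dplyr::bind_rows(
    dplyr::mutate(base, arm = "placebo"),
    dplyr::mutate(base, arm = "treatment")
  )
  tr$x1_fu <- tr$x1_bl + rep(rnorm(50, 0.5, 0.3), 2)
  tr$x2_fu <- tr$x2_bl + rep(rnorm(50, -0.2, 0.1), 2)
  tr$id <- seq_len(nrow(tr))
  expect_equal(pre_rrr(fit, tr, horizon = 5)$rrr_percent, 0, tolerance = 1e-12)
})

test_that("a zero-coefficient marker contributes no RRR", {
  fit <- manual_fit(beta = c(0, 0.5), H0 = 0.1, names_ = c("x1", "x2"))
  tr <- two_patient_trial(shift = -2, p = 3)
  tr$x2_bl <- 0.3; tr$x2_fu <- 0.3
  expect_identical(single_marker_rrr(fit, tr, "x1")$rrr_percent, 0)
})

test_that("single active marker equals the integrated score", {
  fit <- shared_fit("kidney")
  tr <- shared_trial()
  only_uacr <- tr
  for (nm in setdiff(fit$markers$name, "uacr")) {
    only_uacr[[paste0(nm, "_fu")]] <- only_uacr[[paste0(nm, "_bl")]]
  }
  expect_equal(single_marker_rrr(fit, only_uacr, "uacr")$rrr_percent,
               pre_rrr(fit, only_uacr)$rrr_percent, tolerance = 1e-12)
})

test_that("single-marker RRRs do not sum to the integrated RRR", {
  fit <- shared_fit("kidney")
  tr <- shared_trial()
  singles <- vapply(fit$markers$name, function(nm)
    single_marker_rrr(fit, tr, nm)$rrr_percent, numeric(1))
  integrated <- pre_rrr(fit, tr)$rrr_percent
  expect_gt(abs(sum(singles) - integrated), 0.05)
})

test_that("bootstrap CI is seed-stable, ordered, and respects degenerate SEs", {
  fit <- shared_fit("kidney")
  tr <- shared_trial()
  r1 <- bootstrap_ci(fit, tr, n_draws = 100, seed = 81)
  r2 <- bootstrap_ci(fit, tr, n_draws = 100, seed = 81)
  expect_identical(r1$ci_low_percent, r2$ci_low_percent)
  expect_identical(r1$ci_high_percent, r2$ci_high_percent)
  expect_lte(r1$ci_low_percent, r1$ci_high_percent)
  expect_identical(r1$n_bootstrap, 100L)

  # se -> 0 collapses the interval onto the point estimate
  fit0 <- manual_fit(beta = log(2), se = 1e-14, H0 = 0.1)
  tr0 <- two_patient_trial(shift = -1)
  r0 <- bootstrap_ci(fit0, tr0, horizon = 5, n_draws = 50, seed = 82)
  expect_equal(r0$ci_low_percent, r0$rrr_percent, tolerance = 1e-8)
  expect_equal(r0$ci_high_percent, r0$rrr_percent, tolerance = 1e-8)

  # n_draws = 2: percentile CI equals the range of the two draws
  rr <- bootstrap_ci(fit, tr, n_draws = 2, seed = 83)
  draws <- attr(rr, "draws")
  expect_equal(rr$ci_low_percent, min(draws))
  expect_equal(rr$ci_high_percent, max(draws))
})

test_that("pooling over imputations averages points and pools draws", {
  fit <- shared_fit("kidney")
  tr <- shared_trial()
  r <- bootstrap_ci(fit, tr, n_draws = 40, seed = 84)
  p1 <- pool_over_imputations(list(r))
  expect_equal(p1$rrr_percent, r$rrr_percent)
  expect_equal(p1$ci_low_percent, r$ci_low_percent)
  expect_identical(p1$m, 1L)

  p2 <- pool_over_imputations(list(r, r))
  expect_equal(p2$rrr_percent, r$rrr_percent)
  expect_equal(p2$ci_low_percent, r$ci_low_percent, tolerance = 1e-9)
  expect_identical(p2$m, 2L)

  r_other <- bootstrap_ci(fit, tr, marker_subset = "uacr", n_draws = 40,
                          seed = 85)
  expect_error(pool_over_imputations(list(r, r_other)), "different")
})

test_that("RRR is insensitive to the risk horizon under proportional hazards", {
  # exact horizon invariance holds in the rare-event / homogeneous-risk
  # regime; strong risk heterogeneity (the log-UACR tail in the kidney
  # model) lets high-risk patients saturate, so the kidney score drifts
  # mildly with horizon while the CV score is essentially flat
  tr <- shared_trial()
  rrr_cv <- vapply(c(1, 2, 3, 3.8), function(h)
    pre_rrr(shared_fit("cv"), tr, horizon = h)$rrr_percent, numeric(1))
  expect_lt(max(rrr_cv) - min(rrr_cv), 1)
  rrr_kid <- vapply(c(1, 2, 3, 3.8), function(h)
    pre_rrr(shared_fit("kidney"), tr, horizon = h)$rrr_percent, numeric(1))
  expect_lt(max(rrr_kid) - min(rrr_kid), 5)
})

test_that("deepening the UACR reduction strictly increases the kidney RRR", {
  fit <- shared_fit("kidney")
  tr <- shared_trial()
  treat <- tr$arm == "treatment"
  rrr <- vapply(c(1, 0.9, 0.8), function(extra) {
    tr2 <- tr
    tr2$uacr_fu[treat] <- tr2$uacr_fu[treat] * extra
    pre_rrr(fit, tr2)$rrr_percent
  }, numeric(1))
  expect_true(all(diff(rrr) > 0))
})

test_that("vectorized scoring equals a per-patient loop oracle", {
  fit <- shared_fit("kidney")
  tr <- dplyr::slice(shared_trial(), c(1:50, 1501:1550))
  res <- pre_rrr(fit, tr, horizon = 3)
  mk <- fit$markers
  bare_bl <- dplyr::rename_with(tr, ~ sub("_bl$", "", .x), dplyr::ends_with("_bl"))
  bare_fu <- dplyr::rename_with(tr, ~ sub("_fu$", "", .x), dplyr::ends_with("_fu"))
  risk_bl <- vapply(seq_len(nrow(tr)), function(i)
    predict_risk(fit, bare_bl[i, ], 3), numeric(1))
  risk_fu <- vapply(seq_len(nrow(tr)), function(i)
    predict_risk(fit, bare_fu[i, ], 3), numeric(1))
  treat <- tr$arm == "treatment"
  d_p <- mean(risk_fu[!treat]) / mean(risk_bl[!treat]) - 1
  d_t <- mean(risk_fu[treat]) / mean(risk_bl[treat]) - 1
  expect_equal(res$rrr_percent, -100 * (d_t - d_p), tolerance = 1e-12)
  expect_equal(res$mean_risk_placebo_bl, mean(risk_bl[!treat]),
               tolerance = 1e-12)
})

test_that("scoring rejects malformed inputs", {
  fit <- shared_fit("kidney")
  tr <- shared_trial()
  expect_error(pre_rrr(fit, tr, marker_subset = "nope"), "unknown marker")
  expect_error(pre_rrr(fit, dplyr::filter(tr, arm == "placebo")),
               "non-empty")
  tr_na <- tr; tr_na$uacr_fu[1] <- NA
  expect_error(pre_rrr(fit, tr_na), "impute")
})

test_that("result table covers all markers plus the integrated score", {
  fit <- shared_fit("kidney")
  tr <- shared_trial()
  tab <- score_all_markers(fit, tr, n_draws = 20, seed = 86)
  expect_identical(nrow(tab), 9L)
  expect_identical(tab$label[9], "PRE score")
  td <- tidy(tab)
  expect_true(is.character(td$marker_subset))
  # integrated kidney score dominated by the UACR contribution
  expect_gt(tab$rrr_percent[9], tab$rrr_percent[tab$label == "hba1c"])
})
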