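test_that("generation is deterministic given seed and config", {
  cfg <- sim_config(n_background = 200, n_per_arm = 100)
  expect_identical(generate_background_cohort(cfg, seed = 5),
                   generate_background_cohort(cfg, seed = 5))
  expect_identical(generate_trial(cfg, seed = 5), generate_trial(cfg, seed = 5))
  expect_false(identical(generate_trial(cfg, seed = 5),
                         generate_trial(cfg, seed = 6)))
})

test_that("event fraction matches closed-form exponential survival under null betas", {
  cfg <- sim_config(
    n_background = 20000,
    true_beta_kidney = zero_beta(), true_beta_cv = zero_beta(),
    baseline_hazard_background = c(kidney = 0.05, cv = 0.05),
    follow_up_years = 4, censoring_rate = 0
  )
  bg <- generate_background_cohort(cfg, seed = 31)
  expected <- 1 - exp(-0.2)   # 1 - exp(-rate * follow_up)
  mc_tol <- 3 * sqrt(expected * (1 - expected) / 20000)
  expect_lt(abs(mean(bg$event_kidney) - expected), mc_tol)
  expect_lt(abs(mean(bg$event_cv) - expected), mc_tol)
})

test_that("default background cohort reproduces the pooled-cohort event fractions", {
  cfg <- sim_config(n_background = 20000)
  bg <- generate_background_cohort(cfg, seed = 32)
  expect_lt(abs(mean(bg$event_kidney) - 0.178), 0.012)
  expect_lt(abs(mean(bg$event_cv) - 0.125), 0.012)
})

test_that("marker marginals converge to the configured means and SDs", {
  cfg <- sim_config(n_background = 20000)
  bg <- generate_background_cohort(cfg, seed = 33)
  mk <- cfg$background_markers
  for (j in seq_len(nrow(mk))) {
    x <- bg[[paste0(mk$name[j], "_bl")]]
    z <- if (mk$transform[j] == "natural_log") log(x) else x
    expect_lt(abs(mean(z) - mk$baseline_mean[j]),
              4 * mk$baseline_sd[j] / sqrt(20000))
    expect_lt(abs(stats::sd(z) / mk$baseline_sd[j] - 1), 0.03)
  }
  expect_true(all(bg$uacr_bl > 0))
  expect_true(all(bg$time_kidney > 0))
  expect_true(all(bg$event_kidney %in% 0:1))
})

test_that("trial reproduces the configured placebo-corrected marker shifts", {
  cfg <- sim_config(n_per_arm = 20000)
  tr <- generate_trial(cfg, seed = 34)
  treat <- tr$arm == "treatment"
  pc_change <- function(col_bl, col_fu, log_scale = FALSE) {
    d <- if (log_scale) log(tr[[col_fu]]) - log(tr[[col_bl]]) else
      tr[[col_fu]] - tr[[col_bl]]
    mean(d[treat]) - mean(d[!treat])
  }
  expect_lt(abs(pc_change("hba1c_bl", "hba1c_fu") - (-1.4)), 0.05)
  expect_lt(abs(pc_change("sbp_bl", "sbp_fu") - (-3.0)), 0.5)
  expect_lt(abs(pc_change("weight_bl", "weight_fu") - (-2.3)), 0.25)
  expect_lt(abs(pc_change("hb_bl", "hb_fu") - (-2.6)), 0.5)
  # geometric-mean UACR ratio ~ 0.868 (a 13.2% reduction)
  gm_ratio <- exp(pc_change("uacr_bl", "uacr_fu", log_scale = TRUE))
  expect_lt(abs(gm_ratio - 0.868), 0.02)
})

test_that("null treatment shifts make the two arms exchangeable", {
  mk <- leader_markers()
  mk$treatment_shift <- 0
  cfg <- sim_config(markers = mk, n_per_arm = 8000)
  tr <- generate_trial(cfg, seed = 35)
  treat <- tr$arm == "treatment"
  d <- (log(tr$uacr_fu) - log(tr$uacr_bl))
  diff <- mean(d[treat]) - mean(d[!treat])
  se <- stats::sd(d) * sqrt(2 / 8000)
  expect_lt(abs(diff), 4 * se)
  # log hazard ratio between arms centred on 0
  fit <- survival::coxph(
    survival::Surv(time_kidney, event_kidney) ~ I(arm == "treatment"),
    data = tr)
  expect_lt(abs(unname(coef(fit))), 4 * sqrt(diag(vcov(fit))))
})

test_that("natural-log round trip returns stored native values exactly", {
  cfg <- sim_config(n_per_arm = 50)
  tr <- generate_trial(cfg, seed = 36)
  expect_identical(exp(log(tr$uacr_bl)), tr$uacr_bl)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_background = 0), "positive")
  R <- default_marker_correlation()
  R[1, 2] <- 0.9  # asymmetric
  expect_error(sim_config(marker_correlation = R), "symmetric")
  R2 <- matrix(0.99, 8, 8); diag(R2) <- 1; R2[1, 2] <- R2[2, 1] <- -0.99
  expect_error(sim_config(marker_correlation = R2), "positive semi-definite")
  expect_error(sim_config(baseline_hazard_trial = c(kidney = -1, cv = 0.1)),
               "nonnegative")
  expect_error(
    sim_config(missingness = tibble::tibble(marker = "uacr", rate = 1.2,
                                            mechanism = "MCAR")),
    "\\[0, 1\\]")
})

test_that("missingness injection hits the configured rates and mechanisms", {
  base_cfg <- function(ms) sim_config(n_per_arm = 500, missingness = ms)

  cfg0 <- base_cfg(tibble::tibble(marker = "uacr", rate = 0, mechanism = "MCAR"))
  tr <- generate_trial(cfg0, seed = 40)
  expect_identical(inject_missingness(tr, cfg0, seed = 41), tr)

  cfg1 <- base_cfg(tibble::tibble(marker = "hb", rate = 1, mechanism = "MCAR"))
  out1 <- inject_missingness(tr, cfg1, seed = 41)
  expect_true(all(is.na(out1$hb_fu)))
  expect_false(anyNA(out1$hb_bl))

  cfg3 <- base_cfg(tibble::tibble(marker = "sbp", rate = 0.3, mechanism = "MCAR"))
  out3 <- inject_missingness(tr, cfg3, seed = 42)
  n_miss <- sum(is.na(out3$sbp_fu))
  expect_lt(abs(n_miss - 300), 3 * sqrt(1000 * 0.3 * 0.7) + 1)

  # MAR: missingness increases with the baseline value
  cfg4 <- base_cfg(tibble::tibble(marker = "uacr", rate = 0.3, mechanism = "MAR"))
  out4 <- inject_missingness(tr, cfg4, seed = 43)
  expect_lt(abs(mean(is.na(out4$uacr_fu)) - 0.3), 0.06)
  hi <- log(out4$uacr_bl) > stats::median(log(out4$uacr_bl))
  expect_gt(mean(is.na(out4$uacr_fu[hi])), mean(is.na(out4$uacr_fu[!hi])))
  # outcome and baseline columns untouched
  expect_identical(out4$time_kidney, tr$time_kidney)
  expect_identical(out4$uacr_bl, tr$uacr_bl)
})
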