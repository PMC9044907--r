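test_that("responder classification follows the median-reduction rule", {
  # identical change for everyone: every reduction equals the median -> all respond
  tr <- tibble::tibble(
    id = 1:8, arm = rep(c("placebo", "treatment"), each = 4),
    hba1c_bl = 8, hba1c_fu = 7.5
  )
  resp <- classify_responders(tr, "hba1c")
  expect_true(all(resp$responder))

  # continuous changes, even n, no ties -> exactly half respond
  set.seed(90)
  tr2 <- tibble::tibble(
    id = 1:200, arm = rep(c("placebo", "treatment"), each = 100),
    sbp_bl = rnorm(200, 135, 10), sbp_fu = rnorm(200, 132, 10)
  )
  resp2 <- classify_responders(tr2, "sbp")
  expect_identical(sum(resp2$responder), 50L)

  # threshold approximates the analytic median of the change distribution:
  # treatment log-UACR change ~ N(drift + shift, noise_sd)
  cfg <- sim_config(n_per_arm = 4000)
  tr3 <- generate_trial(cfg, seed = 91)
  resp3 <- classify_responders(tr3, "uacr")
  mk <- cfg$markers[cfg$markers$name == "uacr", ]
  analytic_median <- -(mk$placebo_drift + mk$treatment_shift)
  se <- mk$noise_sd * sqrt(pi / 2) / sqrt(4000)
  expect_lt(abs(attr(resp3, "threshold") - analytic_median), 4 * se)
})

test_that("response shifting preserves schema and hits stratum means at the extremes", {
  cfg <- sim_config(n_per_arm = 800)
  tr <- generate_trial(cfg, seed = 92)
  resp <- classify_responders(tr, "uacr")
  ch <- function(d) {
    treat <- d$arm == "treatment"
    mean(log(d$uacr_fu[treat]) - log(d$uacr_bl[treat]))
  }
  sh1 <- shift_response_distribution(tr, "uacr", 1, seed = 93)
  sh0 <- shift_response_distribution(tr, "uacr", 0, seed = 94)
  expect_identical(dim(sh1), dim(tr))
  expect_identical(names(sh1), names(tr))
  expect_identical(sum(sh1$arm == "treatment"), sum(tr$arm == "treatment"))
  mu_resp <- mean(resp$change[resp$responder])
  mu_non <- mean(resp$change[!resp$responder])
  se <- stats::sd(resp$change) / sqrt(400)
  expect_lt(abs(ch(sh1) - mu_resp), 5 * se)
  expect_lt(abs(ch(sh0) - mu_non), 5 * se)
  # placebo arm untouched
  expect_identical(sh1$uacr_fu[sh1$arm == "placebo"],
                   tr$uacr_fu[tr$arm == "placebo"])
  expect_error(shift_response_distribution(tr, "uacr", 1.2), "proportion")
})

test_that("shifting to the observed responder proportion is distributionally neutral", {
  tr <- shared_trial()
  resp <- classify_responders(tr, "uacr")
  p_obs <- mean(resp$responder)
  sh <- shift_response_distribution(tr, "uacr", p_obs, seed = 95)
  treat <- tr$arm == "treatment"
  ks <- suppressWarnings(stats::ks.test(
    log(sh$uacr_fu[sh$arm == "treatment"]) - log(sh$uacr_bl[sh$arm == "treatment"]),
    resp$change))
  expect_lt(unname(ks$statistic), 0.08)
})

test_that("the RRR curve behaves sensibly along the proportion grid", {
  fit <- shared_fit("kidney")
  tr <- shared_trial()
  cur <- simulate_rrr_curve(fit, tr, "uacr", c(0.25, 0.5, 0.75),
                            n_draws = 30, seed = 96)
  expect_s3_class(cur, "pre_scenario_curve")
  expect_identical(nrow(cur), 3L)
  expect_true(all(diff(cur$proportion) > 0))
  # more responders -> larger percent UACR reduction -> larger RRR
  expect_true(all(diff(cur$change) > 0))
  expect_true(all(diff(cur$rrr_percent) > 0))
  # curve brackets the unshifted RRR
  unshifted <- pre_rrr(fit, tr)$rrr_percent
  expect_gt(unshifted, min(cur$rrr_percent))
  expect_lt(unshifted, max(cur$rrr_percent))

  # a null-coefficient marker yields a flat curve at the other markers' RRR
  fit0 <- fit
  fit0$beta[["potassium"]] <- 0
  cur0 <- simulate_rrr_curve(fit0, tr, "potassium", c(0.2, 0.8),
                             n_draws = 30, seed = 97)
  # flat up to treatment-arm resampling noise in the other markers
  expect_lt(abs(diff(cur0$rrr_percent)), 4)
  expect_error(simulate_rrr_curve(fit, tr, "uacr", numeric(0)), "empty")
})

test_that("target inversion interpolates linearly and honours grid points", {
  cur <- tibble::tibble(change = c(10, 40), rrr_percent = c(10, 30))
  expect_equal(required_change_for_target(cur, 20), 25)
  expect_equal(required_change_for_target(cur, 10), 10)
  expect_equal(required_change_for_target(cur, 30), 40)
  expect_error(required_change_for_target(cur, 50), "outside")
})

test_that("inclusion criteria subset trials as specified", {
  tr <- shared_trial()
  all_in <- inclusion_criteria("egfr_bl", -Inf, Inf)
  expect_identical(apply_inclusion_criteria(tr, all_in), tr)
  none <- inclusion_criteria("egfr_bl", -Inf, 0, include_upper = FALSE)
  expect_warning(out <- apply_inclusion_criteria(tr, none), "no patients")
  expect_identical(nrow(out), 0L)
  expect_error(apply_inclusion_criteria(tr, inclusion_criteria("nope")),
               "missing column")

  # kidney-trial-like subset: low eGFR, heavy albuminuria
  sub <- apply_inclusion_criteria(tr, flow_criteria())
  expect_gt(nrow(sub), 0)
  expect_lt(nrow(sub), nrow(tr))
  expect_true(all(sub$egfr_bl >= 25 & sub$egfr_bl <= 75))
  expect_gt(stats::median(sub$uacr_bl), stats::median(tr$uacr_bl))
  expect_lt(stats::median(sub$egfr_bl), stats::median(tr$egfr_bl))

  # disjunction groups: either band qualifies
  either <- inclusion_criteria(column = c("egfr_bl", "egfr_bl"),
                               min = c(-Inf, 90), max = c(40, Inf),
                               group = c(1, 1))
  out2 <- apply_inclusion_criteria(tr, either)
  expect_true(all(out2$egfr_bl <= 40 | out2$egfr_bl >= 90))
})
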