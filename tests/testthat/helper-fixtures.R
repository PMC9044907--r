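# Shared fixtures, built once per test run.

# Hand-constructed fit for arithmetic oracles: one identity marker "x",
# centre 0, a flat Breslow step so H0(horizon) is known exactly.
manual_fit <- function(beta, se = abs(beta) * 0 + 0.1, H0 = 0.1,
                       t_max = 10, outcome = "kidney",
                       names_ = paste0("x", seq_along(beta))) {
  markers <- marker_spec(
    name = names_, unit = "unit",
    transform = rep("identity", length(beta)),
    baseline_mean = rep(0, length(beta)), baseline_sd = rep(1, length(beta))
  )
  structure(
    list(
      outcome = outcome, markers = markers,
      beta = stats::setNames(beta, names_),
      se = stats::setNames(se, names_),
      vcov = diag(se^2, length(beta)),
      covariate_center = stats::setNames(rep(0, length(beta)), names_),
      baseline_cumhaz = tibble::tibble(time = c(1e-6, t_max),
                                       cumhaz = c(H0, H0)),
      n_events = 100L, n_patients = 1000L, iterations = 3L,
      collinearity_warning = FALSE, condition_number = 1
    ),
    class = "pre_cox_fit"
  )
}

# two-patient-per-arm trial on manual_fit markers: placebo unchanged,
# treatment moves marker 1 from 0 to `shift`
two_patient_trial <- function(shift, p = 1) {
  tibble::tibble(
    id = 1:(2 * p), arm = rep(c("placebo", "treatment"), each = p),
    x1_bl = 0, x1_fu = c(rep(0, p), rep(shift, p))
  )
}

# moderate-size shared default-config fixtures (lazy, computed once)
fixture_env <- new.env()

shared_bg <- function() {
  if (is.null(fixture_env$bg)) {
    fixture_env$bg <- generate_background_cohort(
      sim_config(n_background = 4000), seed = 101)
  }
  fixture_env$bg
}

shared_trial <- function() {
  if (is.null(fixture_env$trial)) {
    fixture_env$trial <- generate_trial(
      sim_config(n_per_arm = 1500), seed = 102)
  }
  fixture_env$trial
}

shared_fit <- function(outcome = "kidney") {
  key <- paste0("fit_", outcome)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- fit_cox(shared_bg(), background_markers(), outcome)
  }
  fixture_env[[key]]
}

# config with zeroed treatment effect / betas
zero_beta <- function() {
  b <- default_true_beta("kidney"); b[] <- 0; b
}
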