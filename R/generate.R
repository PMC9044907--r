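#' Generate a synthetic background cohort
#'
#' Draws baseline risk markers from a Gaussian copula with the configured
#' marginals and correlation (natural-log markers are exponentiated, so UACR
#' is log-normal and strictly positive), then draws one time-to-event pair
#' per outcome from a Weibull proportional-hazards model whose linear
#' predictor uses the configured true betas with covariates centred at their
#' configured means.  Follow-up is administratively censored at
#' `follow_up_years` with optional independent exponential dropout.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; defaults to `config$seed`.  Identical seed and
#'   config give byte-identical output.
#' @return A tibble, one row per patient: `id`, `<marker>_bl` columns
#'   (native scale), `egfr_bl`, and `time_kidney`/`event_kidney`,
#'   `time_cv`/`event_cv`.
#' @export
generate_background_cohort <- function(config = sim_config(), seed = NULL) {
  config <- validate_sim_config(config)
  withr::local_seed(seed %||% config$seed)
  mk <- config$background_markers
  n <- config$n_background
  Z <- draw_copula(n, config$marker_correlation)
  X <- sweep(sweep(Z, 2, mk$baseline_sd, `*`), 2, mk$baseline_mean, `+`)
  colnames(X) <- mk$name
  egfr <- draw_egfr(Z[, "uacr"], config$egfr$background_mean,
                    config$egfr$background_sd, config$egfr$cor_log_uacr)

  out <- tibble::tibble(id = seq_len(n))
  for (j in seq_len(nrow(mk))) {
    out[[paste0(mk$name[j], "_bl")]] <- from_model_scale(X[, j], mk$transform[j])
  }
  out$egfr_bl <- egfr
  for (oc in c("kidney", "cv")) {
    lp <- drop(X %*% config$true_beta[[oc]][mk$name]) -
      sum(config$true_beta[[oc]][mk$name] * mk$baseline_mean)
    ev <- draw_event_times(lp, config$baseline_hazard_background[[oc]],
                           config$weibull_shape, config$follow_up_years,
                           config$censoring_rate)
    out[[paste0("time_", oc)]] <- ev$time
    out[[paste0("event_", oc)]] <- ev$event
  }
  out
}

#' Generate a synthetic two-arm trial
#'
#' Baseline markers are drawn as in [generate_background_cohort()] but from
#' the trial marginals.  Follow-up markers are `baseline + placebo_drift +
#' treatment_shift (treatment arm only) + noise` on the transform scale,
#' with noise SD taken from the marker's `noise_sd` (falling back to
#' `noise_sd_factor * baseline_sd`).  Event times are drawn
#' from the *follow-up* linear predictor, so by default the treatment effect
#' on outcomes is purely mediated by the marker shifts — the ground truth a
#' coefficient-transfer score should recover.  `config$direct_effect` can
#' add a non-marker-mediated hazard multiplier to the treatment arm.
#'
#' @inheritParams generate_background_cohort
#' @return A tibble, one row per patient: `id`, `arm` (`"placebo"` or
#'   `"treatment"`), `<marker>_bl`, `<marker>_fu` (native scale),
#'   `egfr_bl`, and time/event columns per outcome.
#' @export
generate_trial <- function(config = sim_config(), seed = NULL) {
  config <- validate_sim_config(config)
  withr::local_seed(seed %||% config$seed)
  mk <- config$markers
  n <- 2L * config$n_per_arm
  arm <- rep(c("placebo", "treatment"), each = config$n_per_arm)
  treat <- as.numeric(arm == "treatment")

  Z <- draw_copula(n, config$marker_correlation)
  X_bl <- sweep(sweep(Z, 2, mk$baseline_sd, `*`), 2, mk$baseline_mean, `+`)
  colnames(X_bl) <- mk$name
  noise <- matrix(stats::rnorm(n * nrow(mk)), n, nrow(mk))
  noise <- sweep(noise, 2, followup_noise_sd(mk, config$noise_sd_factor), `*`)
  X_fu <- X_bl + noise +
    rep(1, n) %o% mk$placebo_drift + treat %o% mk$treatment_shift
  colnames(X_fu) <- mk$name
  egfr <- draw_egfr(Z[, "uacr"], config$egfr$trial_mean,
                    config$egfr$trial_sd, config$egfr$cor_log_uacr)

  out <- tibble::tibble(id = seq_len(n), arm = arm)
  for (j in seq_len(nrow(mk))) {
    out[[paste0(mk$name[j], "_bl")]] <- from_model_scale(X_bl[, j], mk$transform[j])
    out[[paste0(mk$name[j], "_fu")]] <- from_model_scale(X_fu[, j], mk$transform[j])
  }
  out$egfr_bl <- egfr
  for (oc in c("kidney", "cv")) {
    beta <- config$true_beta[[oc]][mk$name]
    lp <- drop(X_fu %*% beta) - sum(beta * mk$baseline_mean) +
      treat * log(config$direct_effect[[oc]])
    ev <- draw_event_times(lp, config$baseline_hazard_trial[[oc]],
                           config$weibull_shape, config$follow_up_years,
                           config$censoring_rate)
    out[[paste0("time_", oc)]] <- ev$time
    out[[paste0("event_", oc)]] <- ev$event
  }
  out
}

#' Delete follow-up marker values according to a missingness design
#'
#' Sets follow-up marker cells to `NA` at the per-marker rates in
#' `config$missingness`.  `MCAR` deletes completely at random; `MAR` makes
#' the deletion probability depend on the patient's *baseline* value of the
#' same marker through a logistic link (slope 1 per baseline SD on the
#' transform scale), with the intercept solved so the marginal rate matches.
#' Baseline, arm and outcome columns are never touched.
#'
#' @param trial A trial tibble from [generate_trial()].
#' @inheritParams generate_background_cohort
#' @return The trial tibble with `NA`s injected in `<marker>_fu` columns.
#' @export
inject_missingness <- function(trial, config, seed = NULL) {
  config <- validate_sim_config(config)
  ms <- config$missingness
  if (is.null(ms) || nrow(ms) == 0) return(trial)
  withr::local_seed(seed %||% (config$seed + 1L))
  mk <- config$markers
  for (i in seq_len(nrow(ms))) {
    rate <- ms$rate[i]
    if (rate == 0) next
    col <- paste0(ms$marker[i], "_fu")
    spec <- mk[mk$name == ms$marker[i], ]
    n <- nrow(trial)
    if (ms$mechanism[i] == "MCAR") {
      p <- rep(rate, n)
    } else {
      z <- (to_model_scale(trial[[paste0(ms$marker[i], "_bl")]], spec$transform) -
              spec$baseline_mean) / spec$baseline_sd
      a <- stats::uniroot(function(a) mean(stats::plogis(a + z)) - rate,
                          c(-30, 30))$root
      p <- stats::plogis(a + z)
    }
    drop_cell <- stats::runif(n) < p
    trial[[col]][drop_cell] <- NA_real_
  }
  trial
}

#' Ground-truth marker-mediated relative risk reduction
#'
#' Computes, in closed form under the true generator model, the relative
#' risk reduction attributable to the treatment-induced marker shifts: for
#' a large simulated trial, the event probability by `horizon` is evaluated
#' for each treatment-arm patient under their factual follow-up markers and
#' under the counterfactual follow-up without the treatment shift (same
#' drift and noise).  This is an independent oracle for the coefficient
#' transfer: it never touches the fitted Cox model.
#'
#' Two reference scales are available: `"counterfactual"` returns
#' `100 * (1 - E[F_factual] / E[F_counterfactual])`, the conventional RRR
#' of counterfactual event rates; `"baseline"` divides the factual-minus-
#' counterfactual risk difference by the mean baseline risk, which is the
#' estimand of the difference-form PRE score (see the methods vignette).
#'
#' @inheritParams generate_background_cohort
#' @param outcome `"kidney"` or `"cv"`.
#' @param horizon Risk horizon in years.
#' @param n_mc Number of Monte-Carlo patients.
#' @param reference Denominator convention (see Details).
#' @return RRR in percent (scalar).
#' @export
true_rrr <- function(config = sim_config(), outcome = c("kidney", "cv"),
                     horizon = 3.5, n_mc = 200000, seed = NULL,
                     reference = c("baseline", "counterfactual")) {
  config <- validate_sim_config(config)
  outcome <- match.arg(outcome)
  reference <- match.arg(reference)
  withr::local_seed(seed %||% (config$seed + 7L))
  mk <- config$markers
  beta <- config$true_beta[[outcome]][mk$name]
  Z <- draw_copula(n_mc, config$marker_correlation)
  X_bl <- sweep(sweep(Z, 2, mk$baseline_sd, `*`), 2, mk$baseline_mean, `+`)
  noise <- matrix(stats::rnorm(n_mc * nrow(mk)), n_mc, nrow(mk))
  noise <- sweep(noise, 2, followup_noise_sd(mk, config$noise_sd_factor), `*`)
  X_cf <- X_bl + noise + rep(1, n_mc) %o% mk$placebo_drift
  X_fact <- X_cf + rep(1, n_mc) %o% mk$treatment_shift

  H0 <- config$baseline_hazard_trial[[outcome]] * horizon^config$weibull_shape
  center <- sum(beta * mk$baseline_mean)
  risk <- function(X) mean(1 - exp(-H0 * exp(drop(X %*% beta) - center)))
  f_bl <- risk(X_bl); f_cf <- risk(X_cf); f_fact <- risk(X_fact)
  denom <- if (reference == "baseline") f_bl else f_cf
  100 * (f_cf - f_fact) / denom
}

#' Observed (outcome-based) relative risk reduction in a trial
#'
#' Kaplan-Meier cumulative incidence by `horizon` per arm;
#' `RRR = 100 * (1 - F_treatment / F_placebo)`.  Used to compare the
#' PRE score's marker-based prediction with what the trial's own outcome
#' data show (e.g. when a direct, non-marker-mediated effect is simulated).
#'
#' @param trial Trial tibble with `arm`, `time_<outcome>`, `event_<outcome>`.
#' @inheritParams true_rrr
#' @return RRR in percent (scalar).
#' @export
observed_rrr <- function(trial, outcome = c("kidney", "cv"), horizon = 3.5) {
  outcome <- match.arg(outcome)
  tm <- trial[[paste0("time_", outcome)]]
  ev <- trial[[paste0("event_", outcome)]]
  cuminc <- function(keep) {
    sf <- survival::survfit(survival::Surv(tm[keep], ev[keep]) ~ 1)
    1 - summary(sf, times = horizon, extend = TRUE)$surv
  }
  f_p <- cuminc(trial$arm == "placebo")
  f_t <- cuminc(trial$arm == "treatment")
  100 * (1 - f_t / f_p)
}

# --- internal draws ---------------------------------------------------------

draw_copula <- function(n, R) {
  L <- chol(R + diag(1e-10, nrow(R)))
  Z <- matrix(stats::rnorm(n * nrow(R)), n, nrow(R)) %*% L
  colnames(Z) <- colnames(R)
  Z
}

draw_egfr <- function(z_uacr, mean, sd, rho) {
  z <- rho * z_uacr + sqrt(1 - rho^2) * stats::rnorm(length(z_uacr))
  pmax(mean + sd * z, 5)
}

# Weibull PH: H(t | x) = rate * t^shape * exp(lp); inversion of H gives the
# event time.  Administrative censoring at follow_up plus optional dropout.
draw_event_times <- function(lp, rate, shape, follow_up, censoring_rate) {
  n <- length(lp)
  if (rate == 0) {
    t_event <- rep(Inf, n)
  } else {
    e <- stats::rexp(n)
    t_event <- (e / (rate * exp(lp)))^(1 / shape)
  }
  t_cens <- if (censoring_rate > 0) {
    pmin(stats::rexp(n, censoring_rate), follow_up)
  } else {
    rep(follow_up, n)
  }
  time <- pmin(t_event, t_cens)
  list(time = pmax(time, 1e-8), event = as.integer(t_event <= t_cens))
}

followup_noise_sd <- function(markers, factor) {
  sd <- markers$noise_sd %||% rep(NA_real_, nrow(markers))
  ifelse(is.na(sd), factor * markers$baseline_sd, sd)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
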