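#' Configuration for the synthetic cohort and trial generator
#'
#' Bundles everything the generator needs to produce a background cohort and
#' a two-arm trial with *known* ground truth: the marker panels, the joint
#' marker correlation, the true log hazard ratios per transformed marker
#' unit for each outcome, baseline hazard rates, follow-up and censoring,
#' and an optional non-marker-mediated ("direct") treatment effect on the
#' hazard.  Defaults emulate a GLP1-RA outcome-trial setting: a pooled
#' high-renal-risk background cohort with ~17.8% kidney and ~12.5%
#' cardiovascular composite events, and a lower-risk trial population.
#'
#' The default baseline hazard rates were calibrated once by simulation so
#' that the default background cohort hits those event fractions under the
#' default betas; they are ordinary config values and can be overridden.
#'
#' @param markers `marker_spec` for the trial population
#'   (default [leader_markers()]).
#' @param background_markers `marker_spec` for the background cohort
#'   (default [background_markers()]).
#' @param marker_correlation Correlation matrix across markers on the
#'   transform scale (Gaussian copula).  Default: 0.1 off-diagonal.
#' @param n_background Number of background-cohort patients.
#' @param n_per_arm Patients per trial arm.
#' @param true_beta_kidney,true_beta_cv Named numeric vectors of true log
#'   hazard ratios per transformed-marker unit, aligned to the marker names.
#' @param baseline_hazard_background,baseline_hazard_trial Named numeric
#'   vectors `c(kidney = , cv = )`: events per person-year at the covariate
#'   centre (configured marker means).
#' @param weibull_shape Shape of the Weibull baseline hazard (1 =
#'   exponential).
#' @param follow_up_years Administrative censoring time.
#' @param censoring_rate Rate of an independent exponential dropout process
#'   (0 disables random censoring).
#' @param direct_effect Named vector `c(kidney = , cv = )` of hazard-ratio
#'   multipliers applied to the treatment arm *on top of* the
#'   marker-mediated effect.  1 means the treatment effect is purely
#'   marker-mediated (the ground truth the PRE score targets); values < 1
#'   add protection the markers cannot see.
#' @param noise_sd_factor Follow-up measurement noise SD as a fraction of
#'   the baseline SD (transform scale).
#' @param missingness Tibble with columns `marker`, `rate`, `mechanism`
#'   (`"MCAR"` or `"MAR"`) describing follow-up missingness; `NULL` for
#'   none.
#' @param egfr List with trial/background eGFR marginals and the (negative)
#'   correlation between eGFR and log-UACR; eGFR is an auxiliary covariate
#'   for inclusion filters, not a Cox covariate.
#' @param seed Default integer seed used by the generator functions when no
#'   explicit seed is supplied.
#'
#' @return A list with class `pre_sim_config`.
#' @export
sim_config <- function(markers = leader_markers(),
                       background_markers = prescore::background_markers(),
                       marker_correlation = default_marker_correlation(markers),
                       n_background = 6355,
                       n_per_arm = 4500,
                       true_beta_kidney = default_true_beta("kidney"),
                       true_beta_cv = default_true_beta("cv"),
                       baseline_hazard_background = c(kidney = 0.0131, cv = 0.0308),
                       baseline_hazard_trial = c(kidney = 0.00073, cv = 0.0372),
                       weibull_shape = 1,
                       follow_up_years = 4,
                       censoring_rate = 0.02,
                       direct_effect = c(kidney = 1, cv = 1),
                       noise_sd_factor = 0.5,
                       missingness = NULL,
                       egfr = list(trial_mean = 79.1, trial_sd = 22.1,
                                   background_mean = 51.2, background_sd = 22.5,
                                   cor_log_uacr = -0.4),
                       seed = 1L) {
  cfg <- list(
    markers = validate_marker_spec(markers),
    background_markers = validate_marker_spec(background_markers),
    marker_correlation = marker_correlation,
    n_background = as.integer(n_background),
    n_per_arm = as.integer(n_per_arm),
    true_beta = list(kidney = true_beta_kidney, cv = true_beta_cv),
    baseline_hazard_background = baseline_hazard_background,
    baseline_hazard_trial = baseline_hazard_trial,
    weibull_shape = weibull_shape,
    follow_up_years = follow_up_years,
    censoring_rate = censoring_rate,
    direct_effect = direct_effect,
    noise_sd_factor = noise_sd_factor,
    missingness = missingness,
    egfr = egfr,
    seed = as.integer(seed)
  )
  class(cfg) <- "pre_sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param config Object to validate.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "pre_sim_config"))
  mk <- config$markers$name
  if (!identical(sort(mk), sort(config$background_markers$name))) {
    stop("trial and background marker panels must name the same markers",
         call. = FALSE)
  }
  if (config$n_background <= 0 || config$n_per_arm <= 0) {
    stop("patient counts must be positive", call. = FALSE)
  }
  R <- config$marker_correlation
  if (!is.matrix(R) || nrow(R) != length(mk) || ncol(R) != length(mk)) {
    stop("marker_correlation must be a ", length(mk), "x", length(mk),
         " matrix", call. = FALSE)
  }
  if (max(abs(R - t(R))) > 1e-8 || any(abs(diag(R) - 1) > 1e-8)) {
    stop("marker_correlation must be symmetric with unit diagonal",
         call. = FALSE)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("marker_correlation is not positive semi-definite", call. = FALSE)
  }
  for (oc in c("kidney", "cv")) {
    b <- config$true_beta[[oc]]
    if (is.null(names(b)) || !setequal(names(b), mk)) {
      stop("true_beta_", oc, " must be named after the markers", call. = FALSE)
    }
    if (config$baseline_hazard_background[[oc]] < 0 ||
        config$baseline_hazard_trial[[oc]] < 0) {
      stop("baseline hazard rates must be nonnegative", call. = FALSE)
    }
  }
  if (config$censoring_rate < 0) stop("censoring_rate must be >= 0", call. = FALSE)
  if (config$weibull_shape <= 0) stop("weibull_shape must be > 0", call. = FALSE)
  if (!is.null(config$missingness)) {
    ms <- config$missingness
    stopifnot(all(c("marker", "rate", "mechanism") %in% names(ms)))
    if (any(ms$rate < 0 | ms$rate > 1)) {
      stop("missingness rates must lie in [0, 1]", call. = FALSE)
    }
    if (any(!ms$mechanism %in% c("MCAR", "MAR"))) {
      stop("missingness mechanism must be 'MCAR' or 'MAR'", call. = FALSE)
    }
    bad <- setdiff(ms$marker, mk)
    if (length(bad)) stop("missingness refers to unknown markers: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  config
}

#' @rdname sim_config
#' @param off_diagonal Common correlation used off the diagonal.
#' @export
default_marker_correlation <- function(markers = leader_markers(),
                                       off_diagonal = 0.1) {
  p <- nrow(markers)
  R <- matrix(off_diagonal, p, p, dimnames = list(markers$name, markers$name))
  diag(R) <- 1
  R
}

#' @rdname sim_config
#' @param outcome `"kidney"` or `"cv"`.
#' @export
default_true_beta <- function(outcome = c("kidney", "cv")) {
  outcome <- match.arg(outcome)
  # log hazard ratios per transformed-marker unit; sized so that the
  # single-marker and integrated predicted RRRs are of the magnitude seen
  # for GLP1-RA trials (albuminuria dominant for the kidney outcome,
  # glycemia/BP relatively more important for the CV outcome)
  if (outcome == "kidney") {
    c(hba1c = 0.020, sbp = 0.006, uacr = 1.00, weight = 0.002,
      hb = -0.005, hdl = -0.20, ldl = 0.04, potassium = 0.25)
  } else {
    c(hba1c = 0.027, sbp = 0.010, uacr = 0.20, weight = 0.004,
      hb = -0.004, hdl = -0.35, ldl = 0.12, potassium = 0.15)
  }
}

#' @export
print.pre_sim_config <- function(x, ...) {
  cat("<pre_sim_config>\n")
  cat("  markers:    ", paste(x$markers$name, collapse = ", "), "\n")
  cat("  background: n =", x$n_background,
      " trial: n =", x$n_per_arm, "per arm\n")
  cat("  follow-up:  ", x$follow_up_years, "years; censoring rate",
      x$censoring_rate, "/yr; Weibull shape", x$weibull_shape, "\n")
  cat("  direct effect (HR): kidney", x$direct_effect[["kidney"]],
      ", cv", x$direct_effect[["cv"]], "\n")
  invisible(x)
}
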