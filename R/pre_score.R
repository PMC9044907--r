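#' Parameter Response Efficacy score: predicted relative risk reduction
#'
#' Transfers the background-cohort Cox coefficients onto a trial's
#' short-term marker changes.  For every patient the absolute outcome risk
#' at `horizon` is predicted twice: from the baseline marker values and
#' from the follow-up values (markers outside `marker_subset` keep their
#' baseline value at both time points).  With arm-level mean risks
#' \eqn{\bar R}, the relative change per arm is
#' \eqn{\Delta_{arm} = (\bar R_{fu} - \bar R_{bl}) / \bar R_{bl}}, and the
#' PRE score is the placebo-adjusted relative risk reduction
#' \deqn{RRR = -100 (\Delta_{treat} - \Delta_{placebo}).}
#' An alternative ratio form
#' \eqn{100 (1 - (1+\Delta_{treat})/(1+\Delta_{placebo}))} is available via
#' `form = "ratio"` for sensitivity analysis; both are exactly zero when no
#' marker changes.
#'
#' @param fit A `pre_cox_fit` from [fit_cox()].
#' @param trial Complete (post-imputation) trial tibble with `arm`,
#'   `<marker>_bl` and `<marker>_fu` columns.
#' @param marker_subset Character vector of marker names whose follow-up
#'   values are used; `NULL` (default) uses all fitted markers — the
#'   integrated PRE score.
#' @param horizon Risk horizon in years (default 3.5).
#' @param form `"difference"` (default) or `"ratio"`; see Details.
#' @return A one-row tibble of class `pre_result`: outcome, marker subset,
#'   arm-level mean risks at baseline and follow-up, and `rrr_percent`.
#'   CI columns are `NA` until [bootstrap_ci()] fills them.
#' @export
pre_rrr <- function(fit, trial, marker_subset = NULL, horizon = 3.5,
                    form = c("difference", "ratio")) {
  form <- match.arg(form)
  prep <- prepare_scoring(fit, trial, marker_subset)
  rrr <- score_rrr(prep$X_bl, prep$X_fu, prep$treat, fit$beta[fit$markers$name],
                   fit$covariate_center, baseline_cumhaz(fit, horizon), form,
                   means = TRUE)
  new_pre_result(
    outcome = fit$outcome, marker_subset = prep$subset, horizon = horizon,
    form = form, means = rrr$means, rrr_percent = rrr$rrr,
    n_patients = nrow(trial)
  )
}

#' @rdname pre_rrr
#' @param marker Single marker name.
#' @export
single_marker_rrr <- function(fit, trial, marker, horizon = 3.5,
                              form = c("difference", "ratio")) {
  if (length(marker) != 1) stop("marker must be a single name", call. = FALSE)
  pre_rrr(fit, trial, marker_subset = marker, horizon = horizon, form = form)
}

#' Parametric-bootstrap confidence interval for the PRE score
#'
#' Draws `n_draws` coefficient vectors, by default with each component an
#' independent Normal centred at the fitted coefficient with its standard
#' error (`mvnormal = TRUE` instead draws from the full multivariate normal
#' with the estimated covariance), recomputes the RRR for every draw with
#' the baseline hazard and covariate centre held fixed, and reports the
#' 2.5th/97.5th percentiles.  Standard errors of zero give a point mass at
#' the fitted coefficient.
#'
#' @inheritParams pre_rrr
#' @param n_draws Number of coefficient draws (default 100).
#' @param seed Integer seed; results are reproducible given the seed.
#' @param mvnormal Draw from the multivariate normal using the full
#'   coefficient covariance instead of independent normals.
#' @param level Confidence level (default 0.95).
#' @return A one-row `pre_result` tibble with `ci_low_percent`,
#'   `ci_high_percent` and `n_bootstrap` filled in; the per-draw RRRs are
#'   kept in the `"draws"` attribute for pooling across imputations.
#' @export
bootstrap_ci <- function(fit, trial, marker_subset = NULL, horizon = 3.5,
                         n_draws = 100, seed = 1L,
                         form = c("difference", "ratio"),
                         mvnormal = FALSE, level = 0.95) {
  form <- match.arg(form)
  if (n_draws < 2) stop("n_draws must be at least 2", call. = FALSE)
  prep <- prepare_scoring(fit, trial, marker_subset)
  beta_hat <- fit$beta[fit$markers$name]
  se <- fit$se[fit$markers$name]
  H0 <- baseline_cumhaz(fit, horizon)

  withr::local_seed(seed)
  p <- length(beta_hat)
  if (mvnormal) {
    L <- chol(fit$vcov + diag(1e-12, p))
    B <- matrix(rep(beta_hat, each = n_draws), n_draws, p) +
      matrix(stats::rnorm(n_draws * p), n_draws, p) %*% L
  } else {
    B <- matrix(rep(beta_hat, each = n_draws), n_draws, p) +
      sweep(matrix(stats::rnorm(n_draws * p), n_draws, p), 2, se, `*`)
  }
  colnames(B) <- names(beta_hat)

  point <- score_rrr(prep$X_bl, prep$X_fu, prep$treat, beta_hat,
                     fit$covariate_center, H0, form, means = TRUE)
  draws <- score_rrr_draws(prep$X_bl, prep$X_fu, prep$treat, B,
                           fit$covariate_center, H0, form)
  alpha <- (1 - level) / 2
  ci <- stats::quantile(draws, c(alpha, 1 - alpha), names = FALSE, type = 1)
  new_pre_result(
    outcome = fit$outcome, marker_subset = prep$subset, horizon = horizon,
    form = form, means = point$means, rrr_percent = point$rrr,
    ci_low_percent = ci[1], ci_high_percent = ci[2],
    n_bootstrap = n_draws, n_patients = nrow(trial), draws = draws
  )
}

#' Pool PRE results across multiply-imputed datasets
#'
#' The pooled point estimate is the mean of the per-imputation RRRs; the
#' confidence interval is taken from the percentiles of all bootstrap draws
#' pooled across imputations, so between-imputation variability widens the
#' interval.  All results must share outcome, marker subset, horizon and
#' form.
#'
#' @param results List of `pre_result` rows from [bootstrap_ci()] (or
#'   [pre_rrr()]; then no CI is produced).
#' @param level Confidence level.
#' @return A one-row `pre_result` tibble with `m` set to the number of
#'   imputations.
#' @export
pool_over_imputations <- function(results, level = 0.95) {
  stopifnot(length(results) >= 1)
  first <- results[[1]]
  for (r in results) {
    stopifnot(inherits(r, "pre_result"))
    if (!identical(r$outcome, first$outcome) ||
        !setequal(r$marker_subset[[1]], first$marker_subset[[1]]) ||
        !identical(r$horizon, first$horizon) ||
        !identical(attr(r, "form"), attr(first, "form"))) {
      stop("cannot pool PRE results with different outcome, marker subset, ",
           "horizon or form", call. = FALSE)
    }
  }
  rrr <- mean(vapply(results, function(r) r$rrr_percent, numeric(1)))
  mean_col <- function(col) {
    mean(vapply(results, function(r) r[[col]], numeric(1)))
  }
  means <- c(placebo_bl = mean_col("mean_risk_placebo_bl"),
             placebo_fu = mean_col("mean_risk_placebo_fu"),
             treat_bl = mean_col("mean_risk_treat_bl"),
             treat_fu = mean_col("mean_risk_treat_fu"))
  draws <- unlist(lapply(results, attr, "draws"))
  ci <- if (length(draws)) {
    alpha <- (1 - level) / 2
    stats::quantile(draws, c(alpha, 1 - alpha), names = FALSE, type = 1)
  } else {
    c(NA_real_, NA_real_)
  }
  new_pre_result(
    outcome = first$outcome, marker_subset = first$marker_subset[[1]],
    horizon = first$horizon, form = attr(first, "form"), means = means,
    rrr_percent = rrr, ci_low_percent = ci[1], ci_high_percent = ci[2],
    n_bootstrap = if (length(draws)) length(draws) else NA_integer_,
    n_patients = first$n_patients, m = length(results), draws = draws
  )
}

#' Score every single marker plus the integrated PRE score
#'
#' Convenience wrapper producing a result table with one row per marker
#' and a final `"PRE score"` row for the integrated set — the layout of a
#' forest/bar chart of single-marker versus integrated predictions.
#'
#' @inheritParams bootstrap_ci
#' @param n_draws Draws per marker; set to `NULL` to skip CIs.
#' @return A `pre_result` tibble with `length(markers) + 1` rows.
#' @export
score_all_markers <- function(fit, trial, horizon = 3.5, n_draws = 100,
                              seed = 1L, form = c("difference", "ratio")) {
  form <- match.arg(form)
  subsets <- c(as.list(fit$markers$name), list(fit$markers$name))
  labels <- c(fit$markers$name, "PRE score")
  rows <- purrr::imap(subsets, function(sub, i) {
    r <- if (is.null(n_draws)) {
      pre_rrr(fit, trial, sub, horizon = horizon, form = form)
    } else {
      bootstrap_ci(fit, trial, sub, horizon = horizon, n_draws = n_draws,
                   seed = seed + i, form = form)
    }
    r$label <- labels[i]
    r
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- unique(c("pre_result", class(out)))
  out
}

# --- scoring internals ------------------------------------------------------

prepare_scoring <- function(fit, trial, marker_subset) {
  stopifnot(inherits(fit, "pre_cox_fit"))
  if (!"arm" %in% names(trial)) stop("trial has no 'arm' column", call. = FALSE)
  subset <- marker_subset %||% fit$markers$name
  unknown <- setdiff(subset, fit$markers$name)
  if (length(unknown)) {
    stop("unknown marker name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  treat <- trial$arm == "treatment"
  if (!any(treat) || all(treat)) {
    stop("both trial arms must be non-empty", call. = FALSE)
  }
  X_bl <- marker_matrix(trial, fit$markers, suffix = "_bl")
  X_fu <- X_bl
  fu_all <- marker_matrix(trial, fit$markers, suffix = "_fu")
  X_fu[, subset] <- fu_all[, subset]
  if (anyNA(X_bl) || anyNA(X_fu)) {
    stop("trial marker columns contain missing values; impute first",
         call. = FALSE)
  }
  list(X_bl = X_bl, X_fu = X_fu, treat = treat, subset = subset)
}

risk_from_lp <- function(lp, H0) 1 - exp(-H0 * exp(lp))

rrr_from_means <- function(means, form) {
  d_placebo <- means[["placebo_fu"]] / means[["placebo_bl"]] - 1
  d_treat <- means[["treat_fu"]] / means[["treat_bl"]] - 1
  if (form == "difference") {
    -100 * (d_treat - d_placebo)
  } else {
    100 * (1 - (1 + d_treat) / (1 + d_placebo))
  }
}

score_rrr <- function(X_bl, X_fu, treat, beta, center, H0, form, means = FALSE) {
  lp_bl <- drop(sweep(X_bl, 2, center) %*% beta)
  lp_fu <- drop(sweep(X_fu, 2, center) %*% beta)
  r_bl <- risk_from_lp(lp_bl, H0)
  r_fu <- risk_from_lp(lp_fu, H0)
  m <- c(placebo_bl = mean(r_bl[!treat]), placebo_fu = mean(r_fu[!treat]),
         treat_bl = mean(r_bl[treat]), treat_fu = mean(r_fu[treat]))
  list(rrr = rrr_from_means(m, form), means = m)
}

# vectorized over draws: lp matrices are n x n_draws
score_rrr_draws <- function(X_bl, X_fu, treat, B, center, H0, form) {
  Xc_bl <- sweep(X_bl, 2, center)
  Xc_fu <- sweep(X_fu, 2, center)
  R_bl <- risk_from_lp(Xc_bl %*% t(B), H0)
  R_fu <- risk_from_lp(Xc_fu %*% t(B), H0)
  m_pb <- colMeans(R_bl[!treat, , drop = FALSE])
  m_pf <- colMeans(R_fu[!treat, , drop = FALSE])
  m_tb <- colMeans(R_bl[treat, , drop = FALSE])
  m_tf <- colMeans(R_fu[treat, , drop = FALSE])
  d_p <- m_pf / m_pb - 1
  d_t <- m_tf / m_tb - 1
  if (form == "difference") -100 * (d_t - d_p) else 100 * (1 - (1 + d_t) / (1 + d_p))
}

new_pre_result <- function(outcome, marker_subset, horizon, form, means,
                           rrr_percent, ci_low_percent = NA_real_,
                           ci_high_percent = NA_real_,
                           n_bootstrap = NA_integer_, n_patients = NA_integer_,
                           m = NA_integer_, draws = NULL) {
  out <- tibble::tibble(
    outcome = outcome,
    marker_subset = list(marker_subset),
    mean_risk_placebo_bl = means[["placebo_bl"]],
    mean_risk_placebo_fu = means[["placebo_fu"]],
    mean_risk_treat_bl = means[["treat_bl"]],
    mean_risk_treat_fu = means[["treat_fu"]],
    rrr_percent = rrr_percent,
    ci_low_percent = ci_low_percent,
    ci_high_percent = ci_high_percent,
    n_bootstrap = as.integer(n_bootstrap),
    horizon = horizon,
    n_patients = as.integer(n_patients),
    m = as.integer(m)
  )
  attr(out, "form") <- form
  attr(out, "draws") <- draws
  class(out) <- unique(c("pre_result", class(out)))
  out
}

#' Tidy a PRE-score result
#'
#' @param x A `pre_result`.
#' @param ... Unused.
#' @return A tibble with the marker subset flattened to a comma-separated
#'   string, one row per scored subset.
#' @method tidy pre_result
#' @export
tidy.pre_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$marker_subset <- vapply(out$marker_subset, paste, character(1),
                              collapse = ",")
  out
}

#' @export
print.pre_result <- function(x, digits = 3, ...) {
  cat("<pre_result>  outcome:", unique(x$outcome),
      " horizon:", unique(x$horizon), "years\n")
  show <- tidy.pre_result(x)
  cols <- c(intersect("label", names(show)), "marker_subset", "rrr_percent",
            "ci_low_percent", "ci_high_percent")
  print(as.data.frame(show[cols]), digits = digits, row.names = FALSE)
  invisible(x)
}
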