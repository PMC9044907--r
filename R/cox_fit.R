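#' Fit the multivariable marker-outcome Cox model on a background cohort
#'
#' Estimates the log hazard ratios relating the risk markers to one
#' composite outcome with a Cox proportional hazards model (Efron tie
#' handling), plus the Breslow baseline cumulative hazard.  Markers enter on
#' their model transform scale (natural log for UACR) and are centred at the
#' background-cohort means, so the baseline hazard describes the average
#' background patient and `exp(lp)` is a relative hazard versus that
#' patient.
#'
#' @param background Background-cohort tibble from
#'   [generate_background_cohort()] or [read_background_csv()]; must be
#'   complete in the marker columns.
#' @param markers `marker_spec` naming the markers to enter (default
#'   [background_markers()]).
#' @param outcome `"kidney"` or `"cv"`; selects the `time_*`/`event_*`
#'   columns.
#' @param condition_threshold Condition number of the (scaled) covariate
#'   cross-product above which a collinearity warning is recorded on the
#'   fit.
#' @return An object of class `pre_cox_fit`: coefficient vector `beta`,
#'   standard errors `se`, covariate centre, a Breslow step function for
#'   the baseline cumulative hazard, event/patient counts and convergence
#'   info.  Supports [tidy()], [glance()], `print()`, [predict_risk()].
#' @export
fit_cox <- function(background, markers = background_markers(),
                    outcome = c("kidney", "cv"),
                    condition_threshold = 1e6) {
  markers <- validate_marker_spec(markers)
  outcome <- match.arg(outcome)
  tcol <- paste0("time_", outcome)
  ecol <- paste0("event_", outcome)
  missing_cols <- setdiff(c(tcol, ecol, paste0(markers$name, "_bl")),
                          names(background))
  if (length(missing_cols)) {
    stop("background data is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  X <- marker_matrix(background, markers, suffix = "_bl")
  if (anyNA(X)) {
    stop("background marker columns contain missing values; ",
         "the background cohort must be complete", call. = FALSE)
  }
  if (sum(background[[ecol]]) < 2) {
    stop("need at least 2 events to fit the Cox model", call. = FALSE)
  }

  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  kappa_x <- kappa(crossprod(scale(Xc)), exact = FALSE)
  collinear <- is.finite(kappa_x) && kappa_x > condition_threshold

  surv <- survival::Surv(background[[tcol]], background[[ecol]])
  fit <- survival::coxph(surv ~ Xc, ties = "efron",
                         control = survival::coxph.control(iter.max = 50))
  if (!is.null(fit$info) && !is.null(fit$fail)) {
    stop("Cox model failed to converge", call. = FALSE)
  }
  if (fit$iter >= 50) {
    stop("Cox model did not converge in 50 iterations (iter = ",
         fit$iter, ")", call. = FALSE)
  }
  beta <- stats::setNames(unname(stats::coef(fit)), markers$name)
  se <- stats::setNames(sqrt(diag(stats::vcov(fit))), markers$name)

  bh <- survival::basehaz(fit, centered = FALSE)  # covariates 0 = our centre
  structure(
    list(
      outcome = outcome,
      markers = markers,
      beta = beta,
      se = se,
      vcov = stats::vcov(fit),
      covariate_center = stats::setNames(unname(center), markers$name),
      baseline_cumhaz = tibble::tibble(time = bh$time, cumhaz = bh$hazard),
      n_events = sum(background[[ecol]]),
      n_patients = nrow(background),
      iterations = fit$iter,
      collinearity_warning = collinear,
      condition_number = kappa_x
    ),
    class = "pre_cox_fit"
  )
}

#' Cumulative baseline hazard of a fitted model
#'
#' Step-function evaluation of the Breslow baseline cumulative hazard
#' \eqn{H_0(t)} at the covariate centre; \eqn{H_0(0) = 0} and the function
#' is nondecreasing.
#'
#' @param fit A `pre_cox_fit`.
#' @param time Numeric vector of times (years).
#' @return Numeric vector of cumulative hazards.
#' @export
baseline_cumhaz <- function(fit, time) {
  stopifnot(inherits(fit, "pre_cox_fit"))
  if (any(time < 0)) stop("time must be nonnegative", call. = FALSE)
  f <- stats::stepfun(fit$baseline_cumhaz$time,
                      c(0, fit$baseline_cumhaz$cumhaz), right = FALSE)
  f(time)
}

#' Predict absolute outcome risk at a horizon
#'
#' Returns `1 - exp(-H0(horizon) * exp(lp))` with
#' `lp = sum(beta * (x_transformed - centre))`: the event probability by
#' `horizon` for a patient with the given native-scale marker values.
#'
#' @param fit A `pre_cox_fit`.
#' @param new_data Data frame with one column per fitted marker (native
#'   scale; names may be bare marker names or `<marker>_bl`), or a named
#'   numeric vector for a single patient.
#' @param horizon Risk horizon in years; must lie within the support of the
#'   estimated baseline hazard (no extrapolation).
#' @param beta Optional replacement coefficient vector (used by the
#'   parametric bootstrap); defaults to the fitted `beta`.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_risk <- function(fit, new_data, horizon, beta = NULL) {
  stopifnot(inherits(fit, "pre_cox_fit"))
  if (length(horizon) != 1 || horizon < 0) {
    stop("horizon must be a single nonnegative number", call. = FALSE)
  }
  if (horizon > max(fit$baseline_cumhaz$time)) {
    stop("horizon ", horizon, " lies beyond the last observed time (",
         round(max(fit$baseline_cumhaz$time), 3),
         "); no extrapolation", call. = FALSE)
  }
  if (is.numeric(new_data) && !is.null(names(new_data))) {
    new_data <- tibble::as_tibble(as.list(new_data))
  }
  X <- marker_matrix(new_data, fit$markers, suffix = "")
  beta <- beta %||% fit$beta
  lp <- drop(sweep(X, 2, fit$covariate_center) %*% beta[fit$markers$name])
  H0 <- baseline_cumhaz(fit, horizon)
  1 - exp(-H0 * exp(lp))
}

# Build the transform-scale covariate matrix from native-scale columns.
# Accepts bare marker names or suffixed (`_bl`/`_fu`) columns.
marker_matrix <- function(data, markers, suffix = "_bl") {
  cols <- vapply(markers$name, function(nm) {
    for (cand in unique(c(paste0(nm, suffix), nm))) {
      if (cand %in% names(data)) return(cand)
    }
    stop("no column found for marker '", nm, "'", call. = FALSE)
  }, character(1))
  X <- matrix(NA_real_, nrow(data), nrow(markers),
              dimnames = list(NULL, markers$name))
  for (j in seq_len(nrow(markers))) {
    v <- data[[cols[j]]]
    if (!is.numeric(v)) stop("marker column '", cols[j],
                             "' is not numeric", call. = FALSE)
    X[, j] <- to_model_scale(v, markers$transform[j])
  }
  X
}

#' Serialize / restore a fitted background model
#'
#' The fit is written as plain JSON (marker panel, coefficients, standard
#' errors, covariance, centre, and the baseline-hazard knots) so scoring
#' can run without refitting.
#'
#' @param fit A `pre_cox_fit`.
#' @param path File path.
#' @return `write_cox_fit()` returns `path` invisibly; `read_cox_fit()`
#'   returns the restored `pre_cox_fit`.
#' @export
write_cox_fit <- function(fit, path) {
  stopifnot(inherits(fit, "pre_cox_fit"))
  payload <- list(
    outcome = fit$outcome,
    markers = as.data.frame(fit$markers),
    beta = as.list(fit$beta),
    se = as.list(fit$se),
    vcov = unclass(fit$vcov),
    covariate_center = as.list(fit$covariate_center),
    baseline_cumhaz = as.data.frame(fit$baseline_cumhaz),
    n_events = fit$n_events,
    n_patients = fit$n_patients,
    iterations = fit$iterations,
    collinearity_warning = fit$collinearity_warning,
    condition_number = fit$condition_number
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cox_fit
#' @export
read_cox_fit <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  markers <- validate_marker_spec(tibble::as_tibble(raw$markers))
  structure(
    list(
      outcome = raw$outcome,
      markers = markers,
      beta = unlist(raw$beta),
      se = unlist(raw$se),
      vcov = matrix(unlist(raw$vcov), length(raw$beta), length(raw$beta)),
      covariate_center = unlist(raw$covariate_center),
      baseline_cumhaz = tibble::as_tibble(raw$baseline_cumhaz),
      n_events = raw$n_events,
      n_patients = raw$n_patients,
      iterations = raw$iterations,
      collinearity_warning = raw$collinearity_warning,
      condition_number = raw$condition_number
    ),
    class = "pre_cox_fit"
  )
}

#' @export
print.pre_cox_fit <- function(x, ...) {
  cat("<pre_cox_fit>  outcome:", x$outcome, "\n")
  cat("  ", x$n_events, "events /", x$n_patients, "patients;",
      x$iterations, "iterations\n")
  if (isTRUE(x$collinearity_warning)) {
    cat("  ! collinearity warning (condition number ",
        format(x$condition_number, digits = 3), ")\n", sep = "")
  }
  print(tidy.pre_cox_fit(x), ...)
  invisible(x)
}

#' Tidy a fitted background Cox model
#'
#' @param x A `pre_cox_fit`.
#' @param ... Unused.
#' @return One row per marker: `term`, `estimate` (log hazard ratio per
#'   transformed unit), `std.error`, `statistic`, `p.value`.
#' @method tidy pre_cox_fit
#' @export
tidy.pre_cox_fit <- function(x, ...) {
  z <- x$beta / x$se
  tibble::tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = unname(x$se),
    statistic = unname(z),
    p.value = unname(2 * stats::pnorm(-abs(z)))
  )
}

#' @rdname tidy.pre_cox_fit
#' @method glance pre_cox_fit
#' @export
glance.pre_cox_fit <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome,
    n_patients = x$n_patients,
    n_events = x$n_events,
    n_markers = length(x$beta),
    iterations = x$iterations,
    collinearity_warning = x$collinearity_warning
  )
}
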