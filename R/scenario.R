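#' Classify treatment-arm patients as responders for one marker
#'
#' The marker change from baseline to follow-up is computed on the model
#' transform scale (log-difference for UACR); the reduction is its negative.
#' A treatment-arm patient is a responder when their reduction is greater
#' than or equal to the median reduction in the treatment arm, so by
#' construction about half the arm responds (ties can perturb the split,
#' and if every patient has the same change, all are responders).
#'
#' @param trial Complete trial tibble.
#' @param marker Marker name.
#' @param markers `marker_spec` giving the transform (default
#'   [leader_markers()]).
#' @return A tibble for the treatment arm: `id`, `change` (transform
#'   scale), `reduction`, `responder` (logical), plus the threshold as the
#'   `"threshold"` attribute (median reduction).
#' @export
classify_responders <- function(trial, marker, markers = leader_markers()) {
  markers <- validate_marker_spec(markers)
  spec <- markers[markers$name == marker, ]
  if (!nrow(spec)) stop("unknown marker '", marker, "'", call. = FALSE)
  bl <- paste0(marker, "_bl"); fu <- paste0(marker, "_fu")
  if (!all(c(bl, fu) %in% names(trial))) {
    stop("trial lacks columns ", bl, "/", fu, call. = FALSE)
  }
  tr <- trial[trial$arm == "treatment", ]
  change <- to_model_scale(tr[[fu]], spec$transform) -
    to_model_scale(tr[[bl]], spec$transform)
  if (anyNA(change)) {
    stop("marker '", marker, "' has missing values; impute first",
         call. = FALSE)
  }
  reduction <- -change
  threshold <- stats::median(reduction)
  out <- tibble::tibble(id = tr$id, change = change, reduction = reduction,
                        responder = reduction >= threshold)
  attr(out, "threshold") <- threshold
  out
}

#' Shift the distribution of marker responses by enriching responders
#'
#' Resamples the treatment arm with replacement so that a fraction `p` of
#' its patients are responders (per [classify_responders()]) and `1 - p`
#' are non-responders, preserving the arm size and all columns; the placebo
#' arm is untouched.  This reweights the whole multivariate patient record,
#' so correlated markers shift together.
#'
#' @inheritParams classify_responders
#' @param p Target responder proportion in `[0, 1]`.
#' @param seed Integer seed.
#' @return A trial tibble with the same dimensions and schema.
#' @export
shift_response_distribution <- function(trial, marker, p, seed = 1L,
                                        markers = leader_markers()) {
  if (length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    stop("p must be a single proportion in [0, 1]", call. = FALSE)
  }
  resp <- classify_responders(trial, marker, markers)
  treat_rows <- which(trial$arm == "treatment")
  n_t <- length(treat_rows)
  n_resp <- round(p * n_t)
  responders <- treat_rows[resp$responder]
  nonresponders <- treat_rows[!resp$responder]
  if (n_resp > 0 && !length(responders)) {
    stop("no responders exist for marker '", marker,
         "' but p > 0 was requested", call. = FALSE)
  }
  if (n_resp < n_t && !length(nonresponders)) {
    stop("no non-responders exist for marker '", marker,
         "' but p < 1 was requested", call. = FALSE)
  }
  withr::local_seed(seed)
  picked <- c(
    if (n_resp > 0) responders[sample.int(length(responders), n_resp,
                                          replace = TRUE)],
    if (n_resp < n_t) nonresponders[sample.int(length(nonresponders),
                                               n_t - n_resp, replace = TRUE)]
  )
  out <- dplyr::bind_rows(trial[trial$arm == "placebo", ], trial[picked, ])
  out$id <- seq_len(nrow(out))
  out
}

#' Trace predicted RRR as a function of the responder proportion
#'
#' For each proportion in `proportions`, the treatment arm is enriched with
#' [shift_response_distribution()], the realized placebo-corrected mean
#' marker change is recorded, and the trial is rescored with
#' [bootstrap_ci()].  For natural-log markers the realized change is also
#' reported as a percent reduction, `100 * (1 - exp(delta_log))`.
#'
#' @inheritParams shift_response_distribution
#' @param fit A `pre_cox_fit`.
#' @param proportions Strictly increasing grid of responder proportions.
#' @param horizon Risk horizon in years.
#' @param n_draws Bootstrap draws per grid point.
#' @return A tibble of class `pre_scenario_curve`: `proportion`,
#'   `mean_change` (transform scale, placebo-corrected), `change` (the
#'   reporting scale: percent reduction for log markers, native units
#'   otherwise), `rrr_percent`, `ci_low_percent`, `ci_high_percent`.
#' @export
simulate_rrr_curve <- function(fit, trial, marker, proportions,
                               horizon = 3.5, n_draws = 100, seed = 1L,
                               markers = leader_markers()) {
  if (!length(proportions)) stop("proportions grid is empty", call. = FALSE)
  if (is.unsorted(proportions, strictly = TRUE)) {
    stop("proportions must be strictly increasing", call. = FALSE)
  }
  spec <- markers[markers$name == marker, ]
  if (!nrow(spec)) stop("unknown marker '", marker, "'", call. = FALSE)
  rows <- purrr::imap(as.list(proportions), function(p, i) {
    shifted <- shift_response_distribution(trial, marker, p,
                                           seed = seed + i, markers = markers)
    delta <- placebo_corrected_change(shifted, marker, spec$transform)
    res <- bootstrap_ci(fit, shifted, marker_subset = NULL, horizon = horizon,
                        n_draws = n_draws, seed = seed + 1000L + i)
    tibble::tibble(
      proportion = p,
      mean_change = delta,
      change = if (spec$transform == "natural_log") 100 * (1 - exp(delta)) else delta,
      rrr_percent = res$rrr_percent,
      ci_low_percent = res$ci_low_percent,
      ci_high_percent = res$ci_high_percent
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "marker") <- marker
  attr(out, "transform") <- spec$transform
  class(out) <- unique(c("pre_scenario_curve", class(out)))
  out
}

placebo_corrected_change <- function(trial, marker, transform) {
  bl <- to_model_scale(trial[[paste0(marker, "_bl")]], transform)
  fu <- to_model_scale(trial[[paste0(marker, "_fu")]], transform)
  treat <- trial$arm == "treatment"
  mean(fu[treat] - bl[treat]) - mean(fu[!treat] - bl[!treat])
}

#' Marker change required to reach a target RRR
#'
#' Inverts an RRR-versus-change curve by linear interpolation on the
#' reporting change scale and returns the smallest change achieving the
#' target.  Exact grid points are returned without interpolation.
#'
#' @param curve A `pre_scenario_curve` from [simulate_rrr_curve()], or any
#'   data frame with `change` and `rrr_percent` columns.
#' @param target_rrr_percent Target RRR in percent.
#' @return The required placebo-corrected change, on the curve's reporting
#'   scale (percent reduction for log markers).
#' @export
required_change_for_target <- function(curve, target_rrr_percent) {
  stopifnot(all(c("change", "rrr_percent") %in% names(curve)))
  rrr <- curve$rrr_percent
  chg <- curve$change
  if (target_rrr_percent < min(rrr) || target_rrr_percent > max(rrr)) {
    stop("target RRR ", target_rrr_percent,
         "% is outside the achievable range [",
         round(min(rrr), 2), ", ", round(max(rrr), 2), "]", call. = FALSE)
  }
  exact <- which(rrr == target_rrr_percent)
  candidates <- chg[exact]
  ord <- order(chg)
  rrr_s <- rrr[ord]; chg_s <- chg[ord]
  for (i in seq_len(length(rrr_s) - 1)) {
    lo <- rrr_s[i]; hi <- rrr_s[i + 1]
    if ((target_rrr_percent > min(lo, hi) && target_rrr_percent < max(lo, hi)) &&
        hi != lo) {
      w <- (target_rrr_percent - lo) / (hi - lo)
      candidates <- c(candidates, chg_s[i] + w * (chg_s[i + 1] - chg_s[i]))
    }
  }
  if (!length(candidates)) {
    stop("target RRR is not crossed by the curve", call. = FALSE)
  }
  min(candidates)
}

#' Build and apply trial inclusion criteria
#'
#' Criteria are a tibble of interval predicates over baseline columns:
#' `column`, `min`, `max` (use `-Inf`/`Inf` for one-sided bounds),
#' optional `include_lower`/`include_upper` (default inclusive) and an
#' optional `group`: predicates in the same group are OR-ed, and the
#' groups are AND-ed together.
#'
#' `flow_criteria()` ships a default emulating a dedicated kidney-outcome
#' trial's entry window — reduced eGFR (25–75 ml/min/1.73m2) with overt
#' albuminuria (baseline UACR 100–5000 mg/g).  The real trial's exact
#' criteria are not published in the source used here; this default is a
#' documented assumption.
#'
#' @param column,min,max,include_lower,include_upper,group Vectors defining
#'   the predicates (recycled to common length).
#' @return `inclusion_criteria()`/`flow_criteria()`: a criteria tibble.
#' @export
inclusion_criteria <- function(column, min = -Inf, max = Inf,
                               include_lower = TRUE, include_upper = TRUE,
                               group = NULL) {
  out <- tibble::tibble(column = as.character(column), min = min, max = max,
                        include_lower = include_lower,
                        include_upper = include_upper)
  out$group <- if (is.null(group)) seq_len(nrow(out)) else group
  if (any(out$min > out$max)) stop("criteria bounds out of order", call. = FALSE)
  if (!nrow(out)) stop("need at least one predicate", call. = FALSE)
  out
}

#' @rdname inclusion_criteria
#' @export
flow_criteria <- function() {
  inclusion_criteria(column = c("egfr_bl", "uacr_bl"),
                     min = c(25, 100), max = c(75, 5000))
}

#' @rdname inclusion_criteria
#' @param trial Trial tibble.
#' @param criteria Criteria tibble from [inclusion_criteria()].
#' @return `apply_inclusion_criteria()`: the subset of `trial` satisfying
#'   the criteria (possibly empty, with a warning).
#' @export
apply_inclusion_criteria <- function(trial, criteria) {
  stopifnot(all(c("column", "min", "max", "group") %in% names(criteria)))
  bad <- setdiff(criteria$column, names(trial))
  if (length(bad)) {
    stop("criteria reference missing column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  keep <- rep(TRUE, nrow(trial))
  for (g in unique(criteria$group)) {
    preds <- criteria[criteria$group == g, ]
    group_ok <- rep(FALSE, nrow(trial))
    for (i in seq_len(nrow(preds))) {
      v <- trial[[preds$column[i]]]
      lo_ok <- if (isTRUE(preds$include_lower[i])) v >= preds$min[i] else v > preds$min[i]
      hi_ok <- if (isTRUE(preds$include_upper[i])) v <= preds$max[i] else v < preds$max[i]
      group_ok <- group_ok | (lo_ok & hi_ok & !is.na(v))
    }
    keep <- keep & group_ok
  }
  out <- trial[keep, ]
  if (!nrow(out)) {
    warning("inclusion criteria select no patients", call. = FALSE)
  }
  out
}
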