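#' Read and write patient tables in the package's CSV dialect
#'
#' One flat CSV per table, one row per patient.  Column dictionary:
#' `id`; `arm` (`"placebo"`/`"treatment"`, trial only); `<marker>_bl` and,
#' for trials, `<marker>_fu` native-scale marker values (`NA` for missing);
#' `egfr_bl` auxiliary covariate; `time_kidney`/`event_kidney` and
#' `time_cv`/`event_cv`.  Writers prepend `#`-comment header lines carrying
#' the seed/config hash passed via `header`; readers skip them.
#'
#' @param path File path.
#' @param markers `marker_spec` defining the expected marker columns.
#' @return A validated tibble.
#' @export
read_trial_csv <- function(path, markers = leader_markers()) {
  df <- read_patient_csv(path)
  validate_patient_table(df, markers, trial = TRUE)
}

#' @rdname read_trial_csv
#' @export
read_background_csv <- function(path, markers = background_markers()) {
  df <- read_patient_csv(path)
  validate_patient_table(df, markers, trial = FALSE)
}

#' @rdname read_trial_csv
#' @param data Tibble to write.
#' @param header Optional named list written as `# key: value` comment
#'   lines (e.g. seed and config hash).
#' @export
write_trial_csv <- function(data, path, header = NULL) {
  write_patient_csv(data, path, header)
}

#' @rdname read_trial_csv
#' @export
write_background_csv <- function(data, path, header = NULL) {
  write_patient_csv(data, path, header)
}

read_patient_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    readr::read_csv(path, comment = "#", show_col_types = FALSE,
                    progress = FALSE),
    error = function(e) stop("could not parse '", path, "' as CSV: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!nrow(df) && !ncol(df)) {
    stop("schema error: '", path, "' is empty", call. = FALSE)
  }
  df
}

validate_patient_table <- function(df, markers, trial) {
  markers <- validate_marker_spec(markers)
  expected <- c("id", paste0(markers$name, "_bl"))
  if (trial) expected <- c(expected, "arm", paste0(markers$name, "_fu"))
  expected <- c(expected, "time_kidney", "event_kidney", "time_cv", "event_cv")
  missing_cols <- setdiff(expected, names(df))
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (oc in c("kidney", "cv")) {
    ev <- df[[paste0("event_", oc)]]
    if (!all(ev %in% c(0, 1))) {
      stop("event_", oc, " must be 0/1", call. = FALSE)
    }
    if (any(df[[paste0("time_", oc)]] <= 0, na.rm = TRUE)) {
      stop("time_", oc, " must be positive", call. = FALSE)
    }
  }
  if (trial && !all(df$arm %in% c("placebo", "treatment"))) {
    stop("arm must be 'placebo' or 'treatment'", call. = FALSE)
  }
  for (nm in markers$name[markers$transform == "natural_log"]) {
    for (suf in c("_bl", if (trial) "_fu")) {
      col <- paste0(nm, suf)
      if (col %in% names(df) && any(df[[col]] <= 0, na.rm = TRUE)) {
        stop("validation error: nonpositive values in ", col, call. = FALSE)
      }
    }
  }
  tibble::as_tibble(df)
}

write_patient_csv <- function(data, path, header = NULL) {
  lines <- character(0)
  if (!is.null(header)) {
    lines <- paste0("# ", names(header), ": ",
                    vapply(header, as.character, character(1)))
  }
  body <- readr::format_csv(data, na = "")
  writeLines(c(lines, sub("\n$", "", body)), path)
  invisible(path)
}

config_hash <- function(config) {
  # stable short fingerprint of the configuration for output headers
  ser <- serialize(lapply(unclass(config), function(x) {
    if (is.data.frame(x)) as.list(as.data.frame(x)) else x
  }), NULL, version = 2)
  sprintf("%08x", sum(as.integer(ser) * seq_along(ser)) %% 2^31)
}

#' Run the full PRE-score pipeline on synthetic data
#'
#' Orchestrates simulate -> inject missingness -> impute -> fit -> score:
#' generates a background cohort and a two-arm trial from `config`, applies
#' the configured missingness and chained-equation PMM imputation, fits the
#' background Cox model per outcome, scores every single marker plus the
#' integrated PRE score on each imputed dataset, and pools across
#' imputations.  All randomness derives from `seed`; a rerun with the same
#' config and seed reproduces every output, and written files carry the
#' seed and a config hash in their header comments.
#'
#' @param config A [sim_config()].
#' @param outcomes Outcomes to score (default both).
#' @param horizon Risk horizon in years.
#' @param n_draws Bootstrap draws per scored subset.
#' @param m,n_iterations,k_donors Imputation settings (see [impute_pmm()]);
#'   imputation is skipped when the trial is complete.
#' @param seed Integer master seed (defaults to `config$seed`).
#' @param output_dir Optional directory; when given, the background, trial
#'   and result tables are written there as CSV.
#' @return A list: `background`, `trial` (with missingness), `imputations`,
#'   `fits` (per outcome), and `results`, a `pre_result` tibble with one
#'   row per marker and outcome plus the integrated score rows.
#' @export
run_pipeline <- function(config = sim_config(), outcomes = c("kidney", "cv"),
                         horizon = 3.5, n_draws = 100, m = 5,
                         n_iterations = 5, k_donors = 5, seed = NULL,
                         output_dir = NULL) {
  config <- validate_sim_config(config)
  seed <- as.integer(seed %||% config$seed)
  outcomes <- match.arg(outcomes, several.ok = TRUE)

  background <- generate_background_cohort(config, seed = seed)
  trial <- generate_trial(config, seed = seed + 1L)
  trial <- inject_missingness(trial, config, seed = seed + 2L)
  imputations <- if (anyNA(trial[grep("_(bl|fu)$", names(trial))])) {
    impute_pmm(trial, config$markers, m = m, n_iterations = n_iterations,
               k_donors = k_donors, seed = seed + 3L)
  } else {
    list(trial)
  }

  fits <- lapply(stats::setNames(outcomes, outcomes), function(oc) {
    fit_cox(background, config$background_markers, outcome = oc)
  })

  results <- purrr::map(outcomes, function(oc) {
    fit <- fits[[oc]]
    subsets <- c(as.list(fit$markers$name), list(fit$markers$name))
    labels <- c(fit$markers$name, "PRE score")
    purrr::imap(subsets, function(sub, i) {
      per_imp <- purrr::imap(imputations, function(dat, j) {
        bootstrap_ci(fit, dat, marker_subset = sub, horizon = horizon,
                     n_draws = n_draws, seed = seed + 100L * i + j)
      })
      pooled <- pool_over_imputations(per_imp)
      pooled$label <- labels[i]
      pooled
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  class(results) <- unique(c("pre_result", class(results)))

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- list(seed = seed, config_hash = config_hash(config))
    write_background_csv(background, file.path(output_dir, "background.csv"), hdr)
    write_trial_csv(trial, file.path(output_dir, "trial.csv"), hdr)
    write_patient_csv(tidy.pre_result(results),
                      file.path(output_dir, "results.csv"), hdr)
  }
  list(background = background, trial = trial, imputations = imputations,
       fits = fits, results = results, seed = seed,
       config_hash = config_hash(config))
}
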