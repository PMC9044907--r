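#' Multiple imputation by chained equations with predictive mean matching
#'
#' Fills missing marker cells (typically follow-up measurements) by the
#' standard chained-equations algorithm: each incomplete variable is
#' regressed, on the model transform scale, on all other marker columns
#' plus a treatment-arm indicator; regression parameters are drawn from
#' their Bayesian posterior (normal-inverse-chi-squared); and each missing
#' cell receives the *observed* value of a donor whose predicted mean is
#' among the `k_donors` closest to the missing cell's predicted mean
#' (type-1 matching, donor chosen uniformly at random).  Because every
#' imputed value is an observed donor value, imputations respect bounds and
#' skewness — the reason the method suits heavily skewed markers such as
#' UACR, which is imputed on the log scale.
#'
#' Variables are visited in increasing order of missingness count (ties by
#' column order); `m` independent chains give `m` completed datasets.
#' Observed cells are never modified, and outcome/arm columns are never
#' imputed.
#'
#' @param trial Trial tibble (columns `arm`, `<marker>_bl`, `<marker>_fu`;
#'   outcome columns are carried through untouched).
#' @param markers `marker_spec` giving the transforms (default
#'   [leader_markers()]).
#' @param m Number of completed datasets (default 5).
#' @param n_iterations Chained-equation sweeps per dataset (default 5).
#' @param k_donors Donor-pool size (default 5).
#' @param seed Integer seed.
#' @return A list of `m` complete trial tibbles.
#' @export
impute_pmm <- function(trial, markers = leader_markers(), m = 5,
                       n_iterations = 5, k_donors = 5, seed = 1L) {
  markers <- validate_marker_spec(markers)
  if (m < 1 || n_iterations < 1 || k_donors < 1) {
    stop("m, n_iterations and k_donors must all be >= 1", call. = FALSE)
  }
  marker_cols <- c(paste0(markers$name, "_bl"), paste0(markers$name, "_fu"))
  marker_cols <- intersect(marker_cols, names(trial))
  if (!length(marker_cols)) stop("no marker columns found", call. = FALSE)
  for (col in marker_cols) {
    if (!is.numeric(trial[[col]])) {
      stop("marker column '", col, "' is not numeric", call. = FALSE)
    }
  }
  transform_of <- function(col) {
    markers$transform[markers$name == sub("_(bl|fu)$", "", col)]
  }
  # work matrix on the transform scale
  W <- matrix(NA_real_, nrow(trial), length(marker_cols),
              dimnames = list(NULL, marker_cols))
  for (col in marker_cols) {
    W[, col] <- to_model_scale(trial[[col]], transform_of(col))
  }
  n_miss <- colSums(is.na(W))
  incomplete <- names(n_miss)[n_miss > 0]
  if (!length(incomplete)) {
    return(replicate(m, trial, simplify = FALSE))
  }
  if (all(n_miss > 0)) {
    stop("at least one marker column must be fully observed", call. = FALSE)
  }
  zero_obs <- names(n_miss)[n_miss == nrow(trial)]
  if (length(zero_obs)) {
    stop("variable(s) with no observed values cannot be imputed: ",
         paste(zero_obs, collapse = ", "), call. = FALSE)
  }
  low_donor <- incomplete[nrow(W) - n_miss[incomplete] < k_donors]
  if (length(low_donor)) {
    stop("fewer than k_donors observed values for: ",
         paste(low_donor, collapse = ", "), call. = FALSE)
  }
  visit <- incomplete[order(n_miss[incomplete])]
  arm_ind <- as.numeric(trial$arm == "treatment")
  miss_idx <- lapply(visit, function(col) which(is.na(W[, col])))
  names(miss_idx) <- visit

  withr::local_seed(seed)
  out <- vector("list", m)
  for (imp in seq_len(m)) {
    Wc <- W
    for (col in visit) {  # initial fill: random observed donors
      mis <- miss_idx[[col]]
      obs <- which(!is.na(W[, col]))
      Wc[mis, col] <- W[sample(obs, length(mis), replace = TRUE), col]
    }
    for (iter in seq_len(n_iterations)) {
      for (col in visit) {
        mis <- miss_idx[[col]]
        obs_rows <- setdiff(seq_len(nrow(Wc)), mis)
        X <- cbind(1, Wc[, setdiff(marker_cols, col), drop = FALSE], arm_ind)
        y_obs <- Wc[obs_rows, col]
        draw <- bayes_lm_draw(X[obs_rows, , drop = FALSE], y_obs)
        yhat_obs <- drop(X[obs_rows, , drop = FALSE] %*% draw$beta_hat)
        yhat_mis <- drop(X[mis, , drop = FALSE] %*% draw$beta_star)
        donors <- pmm_match(yhat_obs, yhat_mis, k_donors)
        Wc[mis, col] <- y_obs[donors]
      }
    }
    completed <- trial
    for (col in visit) {
      mis <- miss_idx[[col]]
      completed[[col]][mis] <- from_model_scale(Wc[mis, col], transform_of(col))
    }
    out[[imp]] <- completed
  }
  out
}

# Bayesian linear regression draw (Jeffreys prior), as in standard MICE:
# sigma*^2 = RSS / chi2_{n-p};  beta* ~ N(beta_hat, sigma*^2 (X'X)^-1)
bayes_lm_draw <- function(X, y) {
  qr_x <- qr(X)
  keep <- qr_x$pivot[seq_len(qr_x$rank)]
  Xk <- X[, keep, drop = FALSE]
  qr_k <- qr(Xk)
  beta_k <- qr.coef(qr_k, y)
  resid <- y - drop(Xk %*% beta_k)
  dof <- max(length(y) - length(beta_k), 1)
  sigma2_star <- sum(resid^2) / stats::rchisq(1, dof)
  XtX_inv <- chol2inv(qr.R(qr_k))
  L <- tryCatch(chol(XtX_inv + diag(1e-12, ncol(Xk))),
                error = function(e) diag(sqrt(diag(XtX_inv))))
  beta_star_k <- beta_k + sqrt(sigma2_star) * drop(stats::rnorm(ncol(Xk)) %*% L)
  beta_hat <- beta_star <- numeric(ncol(X))
  beta_hat[keep] <- beta_k
  beta_star[keep] <- beta_star_k
  list(beta_hat = beta_hat, beta_star = beta_star)
}

# For each predicted mean of a missing cell, pick one of the k observed
# donors with the closest predicted means (uniformly at random among them).
pmm_match <- function(yhat_obs, yhat_mis, k) {
  ord <- order(yhat_obs)
  sorted <- yhat_obs[ord]
  n <- length(sorted)
  k <- min(k, n)
  pos <- findInterval(yhat_mis, sorted)
  vapply(seq_along(yhat_mis), function(i) {
    lo <- max(1, pos[i] - k)
    hi <- min(n, pos[i] + k)
    window <- lo:hi
    d <- abs(sorted[window] - yhat_mis[i])
    cand <- window[order(d)[seq_len(k)]]
    ord[cand[sample.int(length(cand), 1)]]
  }, integer(1))
}
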