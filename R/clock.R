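#' Drop samples with too many missing CpG measurements
#'
#' Removes samples with 10 or more missing beta values (equivalently, keeps
#' samples with at most `max_missing = 9` missing cells), the QC rule used
#' before imputation when building the clock.
#'
#' @param beta Sample-by-CpG methylation matrix (`NA` = missing).
#' @param max_missing Maximum number of missing cells a kept sample may have.
#' @return List with `beta` (filtered matrix) and `dropped` (character
#'   vector of removed sample ids).
#' @export
qc_filter_samples <- function(beta, max_missing = 9L) {
  if (nrow(beta) == 0L) stopf("empty methylation matrix")
  n_missing <- rowSums(is.na(beta))
  keep <- n_missing <= max_missing
  if (!any(keep)) stopf("all samples dropped by the missingness rule")
  list(beta = beta[keep, , drop = FALSE],
       dropped = rownames(beta)[!keep])
}

#' K-nearest-neighbour imputation of missing beta values
#'
#' Each missing cell is replaced by the mean of that CpG's observed values
#' among the `k` nearest samples, with distance measured as the root mean
#' squared difference over mutually observed CpGs (so samples with different
#' missingness patterns remain comparable). Neighbour candidates are
#' restricted to samples with the CpG observed; ties are broken by sample
#' order, so the result is deterministic. A target sample sharing no
#' observed CpG with any candidate falls back to the CpG's overall mean.
#'
#' @param beta Sample-by-CpG methylation matrix (`NA` = missing).
#' @param k Number of neighbours (default 10; must be `< n_samples`).
#' @return A complete matrix of the same shape.
#' @export
knn_impute <- function(beta, k = 10L) {
  k <- check_count(k, "k")
  n <- nrow(beta)
  if (k >= n) stopf("k (%d) must be smaller than the number of samples (%d)",
                    k, n)
  col_obs <- colSums(!is.na(beta))
  if (any(col_obs == 0L)) {
    stopf("cannot impute CpG(s) with no observed value: %s",
          paste(colnames(beta)[col_obs == 0L], collapse = ", "))
  }
  miss <- which(is.na(beta), arr.ind = TRUE)
  if (nrow(miss) == 0L) return(beta)
  col_means <- colMeans(beta, na.rm = TRUE)
  out <- beta
  obs <- !is.na(beta)
  for (i in unique(miss[, 1L])) {
    target_cols <- miss[miss[, 1L] == i, 2L]
    xi <- beta[i, ]
    # squared distances to all samples over mutually observed CpGs
    shared <- obs & matrix(obs[i, ], n, ncol(beta), byrow = TRUE)
    diffs <- sweep(beta, 2L, xi)
    diffs[!shared] <- NA_real_
    n_shared <- rowSums(shared)
    d2 <- rowMeans(diffs^2, na.rm = TRUE)
    d2[i] <- Inf
    d2[n_shared == 0L] <- Inf
    for (j in target_cols) {
      cand <- which(obs[, j] & is.finite(d2))
      if (length(cand) == 0L) {
        out[i, j] <- col_means[j]
        next
      }
      nb <- cand[order(d2[cand])][seq_len(min(k, length(cand)))]
      out[i, j] <- mean(beta[nb, j])
    }
  }
  out
}

# Standardization matching the penalized-regression convention: column SDs
# use the 1/n (not 1/(n-1)) denominator.
sd_n <- function(x) sqrt(colMeans(sweep(x, 2L, colMeans(x))^2))

#' Fit the rDNA methylation clock
#'
#' Elastic-net regression of chronological age on CpG beta values,
#' minimizing `(1/(2n)) * RSS + lambda * (alpha * L1 + ((1-alpha)/2) * L2)`
#' with predictors standardized internally and coefficients reported on the
#' original scale. The penalty path holds 100 values descending four orders
#' of magnitude from `lambda_max = max_j |<x_j, y - mean(y)>| / (n * alpha)`
#' (computed on standardized predictors). The penalty is chosen by k-fold
#' cross-validation with the one-standard-error rule: the largest lambda
#' whose CV mean squared error is within one standard error of the minimum.
#' Folds are assigned by a seeded permutation, as equal in size as possible.
#' Fitting is delegated to glmnet, whose objective uses the same `1/(2n)`
#' convention.
#'
#' @param beta Complete sample-by-CpG matrix (run [qc_filter_samples()] and
#'   [knn_impute()] first).
#' @param ages Chronological ages in years.
#' @param alpha Elastic-net mixing parameter (1 = lasso, 0 = ridge);
#'   default 0.5.
#' @param n_folds Number of CV folds (default 10).
#' @param seed Seed for fold assignment.
#' @param lambda Optional explicit penalty path (overrides the default
#'   path; a single value skips cross-validation and fits at that penalty).
#' @param nlambda,lambda_min_ratio Path length and ratio of smallest to
#'   largest path value.
#' @return An object of class `clock_model`: `intercept`, `weights` (named
#'   vector over all CpGs, zeros included), `alpha`, `lambda`,
#'   `n_features_selected`, `cv` (data frame `lambda`, `cvm`, `cvsd`; `NULL`
#'   when CV was skipped), `metadata` (n_samples, n_folds, seed).
#' @export
fit_clock <- function(beta, ages, alpha = 0.5, n_folds = 10L, seed = 1L,
                      lambda = NULL, nlambda = 100L,
                      lambda_min_ratio = 1e-4) {
  beta <- as.matrix(beta)
  if (anyNA(beta)) stopf("fit_clock() requires a complete matrix; impute first")
  if (length(ages) != nrow(beta)) stopf("ages must match matrix rows")
  if (!all(is.finite(ages))) stopf("ages must be finite")
  if (sd(ages) == 0) stopf("degenerate fit: constant response")
  n <- nrow(beta)
  cv <- NULL
  if (is.null(lambda)) {
    if (n < n_folds) stopf("need n >= n_folds (%d < %d)", n, n_folds)
    xs <- sweep(beta, 2L, colMeans(beta))
    s <- sd_n(beta)
    xs <- sweep(xs, 2L, pmax(s, .Machine$double.eps), "/")
    lambda_max <- max(abs(crossprod(xs, ages - mean(ages)))) / (n * alpha)
    lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                      length.out = nlambda))
    foldid <- with_seed(seed, sample(rep(seq_len(n_folds), length.out = n)))
    cvfit <- glmnet::cv.glmnet(beta, ages, alpha = alpha, lambda = lambda,
                               foldid = foldid, family = "gaussian",
                               type.measure = "mse", standardize = TRUE)
    chosen <- cvfit$lambda.1se
    cv <- data.frame(lambda = cvfit$lambda, cvm = cvfit$cvm,
                     cvsd = cvfit$cvsd)
    fit <- cvfit$glmnet.fit
  } else if (length(lambda) == 1L) {
    chosen <- lambda
    fit <- glmnet::glmnet(beta, ages, alpha = alpha, lambda = lambda,
                          family = "gaussian", standardize = TRUE,
                          thresh = 1e-12)
  } else {
    fit <- glmnet::glmnet(beta, ages, alpha = alpha, lambda = lambda,
                          family = "gaussian", standardize = TRUE)
    chosen <- min(lambda)
  }
  cf <- as.matrix(coef(fit, s = chosen, exact = FALSE))[, 1L]
  weights <- cf[-1L]
  names(weights) <- colnames(beta)
  structure(
    list(intercept = unname(cf[1L]), weights = weights, alpha = alpha,
         lambda = chosen, n_features_selected = sum(weights != 0),
         cv = cv,
         metadata = list(n_samples = n, n_folds = n_folds, seed = seed)),
    class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf(paste0("<clock_model> alpha=%.2f lambda=%.4g, %d/%d features, ",
                     "intercept %.2f years (n=%d)\n"),
              x$alpha, x$lambda, x$n_features_selected, length(x$weights),
              x$intercept, x$metadata$n_samples))
  invisible(x)
}

#' Predict age from a fitted clock
#'
#' Linear predictor `intercept + sum_j beta_ij * w_j`; every matrix must
#' cover the model's CpG columns.
#'
#' @param model A [fit_clock()] model.
#' @param beta Complete sample-by-CpG matrix.
#' @return Named vector of predicted ages (years).
#' @export
predict_age <- function(model, beta) {
  beta <- as.matrix(beta)
  missing_cols <- setdiff(names(model$weights), colnames(beta))
  if (length(missing_cols)) {
    stopf("matrix lacks model CpG column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  drop(beta[, names(model$weights), drop = FALSE] %*% model$weights) +
    model$intercept
}

#' Evaluate clock predictions
#'
#' @param predicted,chronological Ages in years (equal length, n >= 2).
#' @return List of class `clock_metrics`: `mse` (mean squared error,
#'   years^2), `mad` (median absolute difference, years) and `r` (Pearson
#'   correlation of predicted vs chronological age; `NA` when predictions
#'   are constant).
#' @export
evaluate_clock <- function(predicted, chronological) {
  if (length(predicted) != length(chronological)) stopf("length mismatch")
  if (length(predicted) < 2L) stopf("need at least 2 pairs")
  err <- predicted - chronological
  r <- if (sd(predicted) == 0 || sd(chronological) == 0) NA_real_
       else cor(predicted, chronological)
  structure(list(mse = mean(err^2), mad = median(abs(err)), r = r),
            class = "clock_metrics")
}

#' @export
print.clock_metrics <- function(x, ...) {
  cat(sprintf("<clock_metrics> MSE %.2f, MAD %.2f years, r %.3f\n",
              x$mse, x$mad, x$r))
  invisible(x)
}

#' Serialize a clock model to JSON
#'
#' @param model A `clock_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clock_model <- function(model, path) {
  jsonlite::write_json(
    list(intercept = model$intercept,
         weights = as.list(model$weights[model$weights != 0]),
         alpha = model$alpha, lambda = model$lambda,
         n_features_selected = model$n_features_selected,
         cpg_ids = names(model$weights),
         metadata = model$metadata),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a clock model from JSON
#'
#' @param path JSON path written by [write_clock_model()].
#' @return A `clock_model`.
#' @export
read_clock_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- setNames(numeric(length(j$cpg_ids)), j$cpg_ids)
  if (length(j$weights)) weights[names(j$weights)] <- unlist(j$weights)
  structure(
    list(intercept = j$intercept, weights = weights, alpha = j$alpha,
         lambda = j$lambda, n_features_selected = sum(weights != 0),
         cv = NULL, metadata = as.list(j$metadata)),
    class = "clock_model")
}
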