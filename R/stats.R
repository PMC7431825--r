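#' Per-sample regional mean methylation
#'
#' Mean beta value over a region's CpG columns, ignoring missing cells; a
#' sample with no observed cell in the region is reported missing.
#'
#' @param beta Sample-by-CpG methylation matrix (%).
#' @param region Character vector of CpG column ids.
#' @return Named numeric vector, one value per sample.
#' @export
regional_mean <- function(beta, region) {
  missing_cols <- setdiff(region, colnames(beta))
  if (length(missing_cols)) {
    stopf("unknown CpG id(s): %s", paste(missing_cols, collapse = ", "))
  }
  rowMeans(beta[, region, drop = FALSE], na.rm = TRUE) |>
    (\(m) ifelse(is.nan(m), NA_real_, m))()
}

corr_result <- function(r, n, k, covariates = character(0)) {
  df <- n - 2L - k
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df)
  list(r = r, p = p, n = n, df = df, covariates = covariates)
}

pairwise_complete <- function(x, y, covariates = NULL) {
  keep <- !is.na(x) & !is.na(y)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  keep
}

#' Pearson correlation with t-based p-value
#'
#' Product-moment correlation over pairwise-complete observations with a
#' two-sided p-value from the t transform on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors.
#' @return List: `r`, `p`, `n`, `df`, `covariates` (empty).
#' @export
pearson_corr <- function(x, y) {
  keep <- pairwise_complete(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stopf("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stopf("correlation undefined for constant input")
  corr_result(cor(x, y), n, 0L)
}

#' Spearman rank correlation with t-based p-value
#'
#' @inheritParams pearson_corr
#' @return List: `r`, `p`, `n`, `df`, `covariates` (empty).
#' @export
spearman_corr <- function(x, y) {
  keep <- pairwise_complete(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stopf("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stopf("correlation undefined for constant input")
  corr_result(cor(x, y, method = "spearman"), n, 0L)
}

#' Pearson partial correlation given covariates
#'
#' Correlation between the OLS residuals of `x` on the covariates and of `y`
#' on the covariates, with a two-sided p-value from the t transform on
#' `n - 2 - k` degrees of freedom. Used to adjust age-methylation
#' associations for confounders such as BMI and sperm concentration. With no
#' (or constant) covariates this reduces to the plain Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Data frame / matrix of covariates (or `NULL`).
#' @return List: `r`, `p`, `n`, `df`, `covariates` (names).
#' @export
partial_corr <- function(x, y, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0L) return(pearson_corr(x, y))
  covariates <- as.data.frame(covariates)
  # constant covariates carry no information; dropping them keeps df honest
  is_const <- vapply(covariates, function(z) sd(z, na.rm = TRUE) == 0,
                     logical(1))
  covariates <- covariates[, !is_const, drop = FALSE]
  if (ncol(covariates) == 0L) return(pearson_corr(x, y))
  keep <- pairwise_complete(x, y, covariates)
  x <- x[keep]; y <- y[keep]
  covariates <- covariates[keep, , drop = FALSE]
  n <- length(x)
  k <- ncol(covariates)
  if (n < 3L + k) stopf("need at least 3 + k complete observations")
  Z <- cbind(1, as.matrix(covariates))
  if (qr(Z)$rank < ncol(Z)) stopf("degenerate covariates: rank-deficient")
  rx <- stats::lm.fit(Z, x)$residuals
  ry <- stats::lm.fit(Z, y)$residuals
  if (sd(rx) < 1e-10 * max(sd(x), 1) || sd(ry) < 1e-10 * max(sd(y), 1)) {
    stopf("zero residual variance: a variable is collinear with the covariates")
  }
  corr_result(cor(rx, ry), n, k, colnames(covariates))
}

#' Two-group comparison
#'
#' Two-sided Welch t test or Mann-Whitney U test (exact when sample sizes
#' permit and there are no ties, normal approximation otherwise).
#'
#' @param a,b Numeric vectors (each `n >= 2`).
#' @param test `"t"` or `"mannwhitney"`.
#' @return List: `statistic`, `p`, `test`.
#' @export
group_compare <- function(a, b, test = c("t", "mannwhitney")) {
  test <- match.arg(test)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) stopf("each group needs n >= 2")
  if (test == "t") {
    res <- t.test(a, b, var.equal = FALSE)
    list(statistic = unname(res$statistic), p = res$p.value, test = "welch_t")
  } else {
    res <- suppressWarnings(wilcox.test(a, b))
    list(statistic = unname(res$statistic), p = res$p.value,
         test = "mann_whitney_u")
  }
}

# Species maximum life spans used for cross-species scaling. Mouse ages are
# given and interpreted in months; all other species in years.
species_life_spans <- function() {
  c(human = 80, bovine = 20, marmoset = 12, mouse = 28)
}

#' Age as a fraction of species life span
#'
#' Normalizes a donor's age by its species' maximum life span so that aging
#' trajectories can be compared across species (human 80 years, bovine 20
#' years, marmoset 12 years, mouse 28 months). Mouse ages must be supplied
#' in months; all other species in years. Values above 1 are possible for
#' donors beyond the nominal life span.
#'
#' @param age Age (> 0); years, or months for mouse.
#' @param species One of `"human"`, `"mouse"`, `"bovine"`, `"marmoset"`.
#' @return Fraction of life span.
#' @export
relative_age <- function(age, species) {
  ls <- species_life_spans()
  if (length(species) == 1L) species <- rep(species, length(age))
  if (!all(species %in% names(ls))) {
    stopf("unknown species: %s",
          paste(setdiff(species, names(ls)), collapse = ", "))
  }
  if (any(age <= 0)) stopf("age must be > 0")
  unname(age / ls[species])
}

#' Ratio of mean epimutation rates between two sample sets
#'
#' Unweighted mean of per-sample epimutation rates in the numerator set
#' divided by the same mean in the denominator set (e.g. old vs young
#' donors, or A vs G alleles).
#'
#' @param er_numerator,er_denominator Numeric vectors of per-sample
#'   epimutation rates (%) or lists of `allele_summary` objects.
#' @return The fold ratio.
#' @export
er_ratio <- function(er_numerator, er_denominator) {
  as_er <- function(x) {
    if (is.list(x)) {
      vapply(x, function(s) s$epimutation_rate, numeric(1))
    } else as.numeric(x)
  }
  num <- as_er(er_numerator); den <- as_er(er_denominator)
  if (length(num) == 0L || length(den) == 0L) stopf("empty sample set")
  md <- mean(den)
  if (md == 0) stopf("undefined ratio: denominator mean epimutation rate is 0")
  mean(num) / md
}
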