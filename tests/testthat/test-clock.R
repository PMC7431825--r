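make_beta <- function(n, p, seed = 1, missing = 0) {
  set.seed(seed)
  beta <- matrix(runif(n * p, 0, 40), n, p,
                 dimnames = list(sprintf("S%03d", 1:n), paste0("cpg", 1:p)))
  if (missing > 0) beta[matrix(runif(n * p) < missing, n, p)] <- NA_real_
  beta
}

test_that("sample QC drops at 10 missing cells and keeps at 9", {
  beta <- make_beta(5, 53, seed = 2)
  beta[1, 1:10] <- NA   # exactly 10 missing -> dropped
  beta[2, 1:9] <- NA    # exactly 9 missing -> kept
  qc <- qc_filter_samples(beta)
  expect_identical(qc$dropped, "S001")
  expect_true("S002" %in% rownames(qc$beta))

  # no missing anywhere: identity
  beta2 <- make_beta(4, 10)
  qc2 <- qc_filter_samples(beta2)
  expect_identical(qc2$beta, beta2)
  expect_length(qc2$dropped, 0L)

  beta3 <- make_beta(3, 12)
  beta3[, 1:10] <- NA
  expect_error(qc_filter_samples(beta3), "all samples dropped")
})

test_that("KNN imputation matches the exhaustive neighbour-search oracle", {
  # complete input is returned unchanged
  beta <- make_beta(12, 8, seed = 3)
  expect_identical(knn_impute(beta), beta)

  # k = 1 with an exact duplicate sample present: imputed value equals the
  # duplicate's value
  b2 <- make_beta(6, 5, seed = 4)
  b2[2, ] <- b2[1, ]
  b2[1, 3] <- NA
  out <- knn_impute(b2, k = 1)
  expect_equal(out[1, 3], b2[2, 3])

  # hand-checkable 3-sample fixture
  b3 <- rbind(s1 = c(10, 20, NA), s2 = c(11, 21, 30), s3 = c(40, 5, 90))
  colnames(b3) <- paste0("cpg", 1:3)
  out3 <- knn_impute(b3, k = 1)
  expect_equal(out3["s1", "cpg3"], 30)   # s2 is the nearest neighbour

  # random fixtures against the exhaustive oracle
  for (seed in 1:5) {
    b <- make_beta(15, 6, seed = seed, missing = 0.1)
    b <- b[rowSums(is.na(b)) < 6, , drop = FALSE]
    if (any(colSums(!is.na(b)) == 0)) next
    out <- knn_impute(b, k = 4)
    expect_false(anyNA(out))
    miss <- which(is.na(b), arr.ind = TRUE)
    for (r in seq_len(nrow(miss))) {
      expect_equal(out[miss[r, 1], miss[r, 2]],
                   knn_impute_oracle(b, miss[r, 1], miss[r, 2], 4),
                   info = sprintf("seed %d cell (%d,%d)", seed,
                                  miss[r, 1], miss[r, 2]))
    }
  }

  expect_error(knn_impute(make_beta(5, 4), k = 5), "must be smaller")
  b_bad <- make_beta(6, 4); b_bad[, 2] <- NA
  expect_error(knn_impute(b_bad, k = 2), "no observed value")
})

test_that("extreme penalties behave as the theory dictates", {
  beta <- make_beta(40, 5, seed = 6)
  ages <- with(list(), {set.seed(7); runif(40, 25, 66)})

  # huge penalty: all weights zero, intercept = mean age
  m_inf <- fit_clock(beta, ages, lambda = 1e6)
  expect_true(all(m_inf$weights == 0))
  expect_equal(m_inf$intercept, mean(ages), tolerance = 1e-8)
  expect_equal(unname(predict_age(m_inf, beta)),
               rep(mean(ages), 40), tolerance = 1e-8)

  # zero penalty with n > p: coefficients equal ordinary least squares
  m0 <- fit_clock(beta, ages, lambda = 0)
  ols <- coef(lm(ages ~ beta))
  expect_equal(unname(m0$weights), unname(ols[-1]), tolerance = 1e-5)
  expect_equal(m0$intercept, unname(ols[1]), tolerance = 1e-4)
})

test_that("coefficients at fixed lambda match a coordinate-descent oracle", {
  set.seed(8)
  n <- 8; p <- 3
  x <- matrix(rnorm(n * p, 20, 5), n, p,
              dimnames = list(NULL, paste0("cpg", 1:p)))
  y <- 30 + 0.8 * x[, 1] - 0.3 * x[, 2] + rnorm(n)
  lambda <- 0.7; alpha <- 0.5
  m <- fit_clock(x, y, alpha = alpha, lambda = lambda)
  oracle <- enet_cd_oracle(x, y, lambda, alpha)
  expect_equal(unname(m$weights), oracle$coef, tolerance = 1e-5)
  # compare objective values on the standardized scale
  mu <- colMeans(x); s <- sqrt(colMeans(sweep(x, 2, mu)^2))
  xs <- sweep(sweep(x, 2, mu), 2, s, "/")
  sy <- sqrt(mean((y - mean(y))^2))
  obj_fit <- enet_objective(xs, y / sy, mean(y) / sy, m$weights * s / sy,
                            lambda / sy, alpha)
  expect_lt(abs(obj_fit - oracle$objective), 1e-6)
})

test_that("a noiseless linear age signal is recovered almost exactly", {
  set.seed(9)
  n <- 120; p <- 53
  beta <- matrix(runif(n * p, 0, 30), n, p,
                 dimnames = list(sprintf("S%03d", 1:n), paste0("cpg", 1:p)))
  w_true <- rep(0, p); w_true[c(3, 10, 20, 30, 45)] <- c(0.5, 0.8, -0.4, 1, 0.6)
  ages <- 10 + drop(beta %*% w_true)
  m <- fit_clock(beta, ages, seed = 2)
  pred <- predict_age(m, beta)
  metrics <- evaluate_clock(pred, ages)
  expect_lt(metrics$mad, 0.5)
  expect_lt(m$n_features_selected, p)
})

test_that("sparsity is non-increasing along the penalty path", {
  beta <- make_beta(60, 20, seed = 10)
  set.seed(11)
  ages <- 20 + beta[, 1] * 0.5 + beta[, 2] * 0.3 + rnorm(60, 0, 2)
  fit <- glmnet::glmnet(beta, ages, alpha = 0.5)
  nz <- fit$df   # nonzero counts along decreasing lambda
  # allow single-feature wobble from coordinate-descent tolerance
  expect_true(all(diff(nz) >= -1))
  expect_gt(max(nz), min(nz))
})

test_that("fold assignment is seed-stable and drives the only CV randomness", {
  beta <- make_beta(80, 15, seed = 12)
  set.seed(13)
  ages <- 15 + 0.6 * beta[, 4] + rnorm(80, 0, 3)
  m1 <- fit_clock(beta, ages, seed = 42)
  m2 <- fit_clock(beta, ages, seed = 42)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$lambda, m2$lambda)
  expect_identical(m1$cv, m2$cv)
  m3 <- fit_clock(beta, ages, seed = 43)
  # a different seed may move the chosen lambda, but the path is shared
  expect_equal(m1$cv$lambda, m3$cv$lambda)
})

test_that("the one-SE rule picks the largest lambda within one SE of the minimum", {
  beta <- make_beta(90, 25, seed = 14)
  set.seed(15)
  ages <- 20 + 0.4 * beta[, 1] - 0.2 * beta[, 5] + rnorm(90, 0, 2)
  m <- fit_clock(beta, ages, seed = 3)
  cv <- m$cv
  i_min <- which.min(cv$cvm)
  thresh <- cv$cvm[i_min] + cv$cvsd[i_min]
  eligible <- cv$lambda[cv$cvm <= thresh]
  expect_equal(m$lambda, max(eligible))
  expect_gte(m$lambda, cv$lambda[i_min])
})

test_that("predictions are exact dot products and metrics match hand arithmetic", {
  model <- structure(
    list(intercept = 5, weights = c(cpg1 = 1, cpg2 = 0), alpha = 0.5,
         lambda = 1, n_features_selected = 1L, cv = NULL,
         metadata = list()), class = "clock_model")
  beta <- rbind(a = c(cpg1 = 10, cpg2 = 99), b = c(cpg1 = 0, cpg2 = 1))
  expect_equal(unname(predict_age(model, beta)), c(15, 5))
  expect_error(predict_age(model, beta[, 1, drop = FALSE]), "lacks model CpG")

  expect_equal(unclass(evaluate_clock(c(30, 40), c(33, 43)))[1:3],
               list(mse = 9, mad = 3, r = 1))
  m2 <- evaluate_clock(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(m2$mse, m2$mad, m2$r), c(0, 0, 1))
  # five-pair fixture against direct arithmetic
  p5 <- c(30, 35, 50, 44, 61); c5 <- c(28, 40, 47, 44, 66)
  m5 <- evaluate_clock(p5, c5)
  expect_equal(m5$mse, mean((p5 - c5)^2))
  expect_equal(m5$mad, median(abs(p5 - c5)))
  expect_equal(m5$r, cor(p5, c5))
  expect_true(is.na(evaluate_clock(c(2, 2, 2), c(1, 2, 3))$r))
})

test_that("clock models round-trip through JSON", {
  beta <- make_beta(50, 10, seed = 16)
  set.seed(17)
  ages <- 20 + 0.5 * beta[, 2] + rnorm(50, 0, 2)
  m <- fit_clock(beta, ages, seed = 5)
  path <- tempfile(fileext = ".json")
  write_clock_model(m, path)
  back <- read_clock_model(path)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$weights, m$weights)
  expect_equal(back$lambda, m$lambda)
  expect_equal(unname(predict_age(back, beta)), unname(predict_age(m, beta)))
})
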