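# Shared fixtures and independent oracles used across the test files.

# Tiny hand-checkable amplicon: 3 CpGs (positions 3, 11, 19), one non-CpG
# cytosine (position 6) for conversion QC, A/G variant at position 15.
tiny_reference <- function() {
  amplicon_reference("tiny", "test", "TACGTCATTACGTAATTACGAT",
                     cpg_positions = c(3L, 11L, 19L),
                     variant_position = 15L)
}

# Recursive (memoised) Needleman-Wunsch score oracle with the same
# bisulfite-aware scoring and linear gap penalty; independent of the DP
# implementation under test.
nw_score_oracle <- function(read, ref, match = 1, mismatch = -1, gap = -2) {
  r <- strsplit(read, "")[[1]]
  f <- strsplit(ref, "")[[1]]
  memo <- new.env(hash = TRUE)
  sc <- function(a, b) {
    if (a == b || (b == "C" && a == "T")) match else mismatch
  }
  go <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == 0 && j == 0) 0
    else if (i == 0) j * gap
    else if (j == 0) i * gap
    else max(go(i - 1, j - 1) + sc(r[i], f[j]),
             go(i - 1, j) + gap,
             go(i, j - 1) + gap)
    memo[[key]] <- val
    val
  }
  go(length(r), length(f))
}

# Brute-force epimutation rate: explicit loop over reads.
er_oracle <- function(fractions) {
  n_hyper <- 0L
  for (fr in fractions) if (fr > 0.5) n_hyper <- n_hyper + 1L
  100 * n_hyper / length(fractions)
}

# Partial correlation of x and y given one covariate z via inversion of the
# 3x3 correlation matrix (precision-matrix form).
partial_corr_oracle_3x3 <- function(x, y, z) {
  R <- cor(cbind(x, y, z))
  P <- solve(R)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# Mann-Whitney U statistic by O(n^2) all-pairs counting (ties count half).
u_stat_oracle <- function(a, b) {
  u <- 0
  for (ai in a) for (bj in b) {
    u <- u + (ai > bj) + 0.5 * (ai == bj)
  }
  u
}

# Exhaustive KNN-imputation oracle: for one missing cell, search all
# neighbour candidates by RMS distance over mutually observed columns.
knn_impute_oracle <- function(beta, i, j, k) {
  n <- nrow(beta)
  d2 <- rep(Inf, n)
  for (s in seq_len(n)) {
    if (s == i) next
    shared <- which(!is.na(beta[i, ]) & !is.na(beta[s, ]))
    if (length(shared) == 0) next
    d2[s] <- mean((beta[i, shared] - beta[s, shared])^2)
  }
  cand <- which(!is.na(beta[, j]) & is.finite(d2))
  if (length(cand) == 0) return(mean(beta[, j], na.rm = TRUE))
  nb <- cand[order(d2[cand])][seq_len(min(k, length(cand)))]
  mean(beta[nb, j])
}

# Cyclic coordinate-descent elastic net oracle replicating the fitting
# convention of the clock: predictors standardized to unit 1/n variance,
# response scaled by its 1/n standard deviation (the penalty is applied on
# that scale, which is what makes lambda values comparable across data
# sets), objective (1/(2n)) * RSS + lambda * (alpha * L1 + (1-alpha)/2 * L2).
# Coefficients are returned destandardized to the original x/y scale.
enet_cd_oracle <- function(x, y, lambda, alpha, n_iter = 5000, tol = 1e-14) {
  n <- nrow(x)
  mu <- colMeans(x)
  s <- sqrt(colMeans(sweep(x, 2, mu)^2))
  xs <- sweep(sweep(x, 2, mu), 2, s, "/")
  sy <- sqrt(mean((y - mean(y))^2))
  ys <- y / sy
  lam <- lambda / sy
  p <- ncol(xs)
  b0 <- mean(ys)
  c_ <- rep(0, p)
  r <- ys - b0
  soft <- function(z, g) sign(z) * max(abs(z) - g, 0)
  for (it in seq_len(n_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      rho <- mean(xs[, j] * r) + c_[j]   # xs has unit 1/n variance
      new <- soft(rho, lam * alpha) / (1 + lam * (1 - alpha))
      if (new != c_[j]) {
        r <- r - (new - c_[j]) * xs[, j]
        delta <- max(delta, abs(new - c_[j]))
        c_[j] <- new
      }
    }
    if (delta < tol) break
  }
  list(intercept = b0 * sy, coef_std = c_, coef = unname(c_ * sy / s),
       objective = enet_objective(xs, ys, b0, c_, lam, alpha))
}

enet_objective <- function(xs, y, b0, c_, lambda, alpha) {
  n <- nrow(xs)
  rss <- sum((y - b0 - drop(xs %*% c_))^2)
  rss / (2 * n) + lambda * (alpha * sum(abs(c_)) +
                              (1 - alpha) / 2 * sum(c_^2))
}

# Simulate a small, perfectly clean read for the tiny reference: given CpG
# states (1/0) and allele, with full conversion.
tiny_read <- function(meth = c(1L, 1L, 1L), allele = "A",
                      convert_qc_site = TRUE) {
  ref <- prepare_reference(tiny_reference())
  bases <- strsplit(ref$sequence, "")[[1]]
  for (k in seq_along(ref$cpg_positions)) {
    bases[ref$cpg_positions[k]] <- if (meth[k] == 1L) "C" else "T"
  }
  bases[ref$noncpg_c_positions] <- if (convert_qc_site) "T" else "C"
  bases[ref$variant_position] <- allele
  paste(bases, collapse = "")
}
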