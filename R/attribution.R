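#' Variance partitioning of a response across predictor groups
#'
#' Fits an OLS model for every non-empty union of the predictor groups
#' (15 models for 4 groups), records Ezekiel adjusted R-squared, and solves
#' the inclusion-exclusion system for the unique and shared components of
#' every group combination. Components may be slightly negative, which is
#' reported as-is; together with the residual they sum exactly to the
#' full-model adjusted R-squared.
#'
#' @param y Numeric response.
#' @param data data.frame holding all predictor columns.
#' @param groups Named list mapping group name -> character vector of
#'   column names; groups must be non-empty and disjoint.
#' @return List: `components` (named vector, names like `"MA"` for unique
#'   fractions and `"MA:Env"` for shared), `adj_r2_union` per union model,
#'   `residual` = 1 - adjusted R2 of the full model.
#' @export
variance_partition <- function(y, data, groups) {
  if (length(groups) < 2 || length(groups) > 4)
    stop("between 2 and 4 predictor groups supported")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be named")
  vars <- unlist(groups)
  if (anyDuplicated(vars)) stop("groups must be disjoint")
  if (!all(vars %in% names(data))) stop("unknown predictor columns")
  n <- length(y)
  k <- length(groups)
  gn <- names(groups)
  subsets <- lapply(seq_len(2^k - 1), function(m) which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0))
  ## adjusted R2 of each union model
  aR2 <- vapply(subsets, function(s) {
    cols <- unlist(groups[s])
    X <- as.matrix(data[cols])
    qx <- qr(cbind(1, X))
    if (qx$rank < ncol(X) + 1)
      warning("collinear columns in a sub-model; adjusted R2 uses matrix rank")
    r2 <- ols_r2(y, X)
    adj_r2(r2, n, qx$rank - 1)
  }, numeric(1))
  ## component c_S for each non-empty S solves:
  ## aR2(union U) = sum over S intersecting U of c_S
  nm <- vapply(subsets, function(s) paste(gn[s], collapse = ":"), character(1))
  A <- matrix(0, 2^k - 1, 2^k - 1)
  for (u in seq_along(subsets))
    for (s in seq_along(subsets))
      A[u, s] <- as.numeric(length(intersect(subsets[[s]], subsets[[u]])) > 0)
  comp <- solve(A, aR2)
  names(comp) <- nm
  full <- aR2[length(aR2)]
  list(components = comp, adj_r2_union = setNames(aR2, nm),
       residual = 1 - full, full_adj_r2 = full)
}

#' LMG relative importance of regression predictors
#'
#' Decomposes the model R-squared over predictors by averaging each
#' predictor's sequential R-squared increase over all `p!` orderings
#' (computed via the subset formulation, so `2^p` OLS fits). Shares always
#' sum to the full-model R-squared. For `p > 8` exact enumeration is
#' refused; use `sampling = TRUE` to average over sampled orderings.
#'
#' @param y Numeric response.
#' @param X Matrix or data.frame of predictors.
#' @param sampling Use sampled orderings for large p (default `FALSE`).
#' @param n_sample Number of sampled orderings when `sampling`.
#' @param seed Seed for sampling mode.
#' @return Named vector of LMG shares (on the R-squared scale).
#' @export
lmg_importance <- function(y, X, sampling = FALSE, n_sample = 5000, seed = 1) {
  X <- as.matrix(X)
  p <- ncol(X)
  n <- length(y)
  if (n <= p + 1) stop("need n > p + 1 observations")
  vn <- colnames(X) %||% paste0("x", seq_len(p))
  if (p > 8 && !sampling)
    stop("p > 8: exact enumeration over orderings refused; set sampling = TRUE")
  if (p > 8) {
    shares <- setNames(numeric(p), vn)
    local_seed(sub_seed(seed, "lmg"), {
      for (b in seq_len(n_sample)) {
        ord <- sample(p)
        r2p <- 0
        for (idx in seq_len(p)) {
          cols <- ord[seq_len(idx)]
          r2c <- ols_r2(y, X[, cols, drop = FALSE])
          shares[ord[idx]] <- shares[ord[idx]] + (r2c - r2p)
          r2p <- r2c
        }
      }
    })
    return(shares / n_sample)
  }
  ## R2 for all subsets, coded by bitmask
  r2 <- numeric(2^p)
  for (m in seq_len(2^p - 1)) {
    cols <- which(bitwAnd(m, 2^(seq_len(p) - 1)) > 0)
    r2[m + 1] <- ols_r2(y, X[, cols, drop = FALSE])
  }
  shares <- setNames(numeric(p), vn)
  for (jj in seq_len(p)) {
    others <- setdiff(seq_len(p), jj)
    for (m in 0:(2^(p - 1) - 1)) {
      s <- length(others)
      cols <- others[which(bitwAnd(m, 2^(seq_len(s) - 1)) > 0)]
      sz <- length(cols)
      w <- factorial(sz) * factorial(p - sz - 1) / factorial(p)
      m_with <- sum(2^(c(cols, jj) - 1))
      m_without <- sum(2^(cols - 1))
      shares[jj] <- shares[jj] + w * (r2[m_with + 1] - r2[m_without + 1])
    }
  }
  shares
}

#' Partial correlation controlling for a set of covariates
#'
#' Correlation between the residuals of `y` and `x` after OLS regression on
#' the controls (equivalently the scaled negative off-diagonal of the
#' precision matrix, available as `method = "precision"`); the p-value uses
#' the t distribution on `n - #controls - 2` df.
#'
#' @param y,x Numeric vectors.
#' @param controls data.frame/matrix of control variables (may have zero
#'   columns for a plain Pearson correlation).
#' @param method `"residual"` (default) or `"precision"`.
#' @return List: `r`, `p`, `df`.
#' @export
partial_correlation <- function(y, x, controls = NULL,
                                method = c("residual", "precision")) {
  method <- match.arg(method)
  Z <- if (is.null(controls)) matrix(numeric(0), length(y), 0)
       else as.matrix(controls)
  if (ncol(Z) > 0) {
    for (j in seq_len(ncol(Z)))
      if (isTRUE(all.equal(unname(Z[, j]), unname(x))))
        stop("x must not appear among the controls")
  }
  n <- length(y)
  q <- ncol(Z)
  if (n <= q + 3) stop("need n > #controls + 3")
  r <- if (method == "residual") {
    ry <- if (q) stats::lm.fit(cbind(1, Z), y)$residuals else y - mean(y)
    rx <- if (q) stats::lm.fit(cbind(1, Z), x)$residuals else x - mean(x)
    cor(ry, rx)
  } else {
    P <- solve(cov(cbind(y = y, x = x, Z)))
    -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  }
  df <- n - q - 2
  tt <- r * sqrt(df / pmax(1 - r^2, 1e-300))
  list(r = r, p = 2 * pt(-abs(tt), df), df = df)
}

#' Mantel test between two distance matrices
#'
#' Spearman correlation of the upper triangles with significance from joint
#' row/column permutations of the second matrix (via [vegan::mantel()];
#' `p = (1 + #permuted >= observed) / (1 + n_perm)`).
#'
#' @param d1,d2 `dist` objects or symmetric matrices of the same size with
#'   zero diagonals.
#' @param method Correlation method (default `"spearman"`).
#' @param n_perm Permutations (default 999).
#' @param seed Integer seed.
#' @return List: `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, method = "spearman", n_perm = 999, seed = 1) {
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!all(dim(m1) == dim(m2))) stop("distance matrices must match in size")
  check_dist <- function(m) {
    if (max(abs(m - t(m))) > 1e-8 || any(abs(diag(m)) > 1e-12))
      stop("inputs must be symmetric with zero diagonal")
  }
  check_dist(m1); check_dist(m2)
  res <- local_seed(sub_seed(seed, "mantel"), suppressMessages(
    vegan::mantel(as.dist(m1), as.dist(m2), method = method,
                  permutations = n_perm)))
  list(r = unname(res$statistic), p = res$signif, n_perm = n_perm)
}

#' Random-forest permutation importance with significance
#'
#' Fits a regression forest (via [ranger::ranger()]) with out-of-bag
#' permutation importance; each variable's significance is the fraction of
#' `n_perm` response-permuted refits whose importance for that variable
#' reaches the observed one, using the `(1 + b) / (1 + B)` estimator.
#'
#' @param y Numeric response (n >= 10, non-constant).
#' @param X data.frame of predictors.
#' @param n_trees Trees per forest (default 500).
#' @param n_perm Response permutations for the null (default 99).
#' @param seed Integer seed.
#' @return data.frame: variable, importance, p.
#' @export
rf_importance <- function(y, X, n_trees = 500, n_perm = 99, seed = 1) {
  if (length(y) < 10) stop("need at least 10 observations")
  if (sd(y) == 0) stop("constant response")
  df <- data.frame(.y = y, X, check.names = FALSE)
  fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                        num.trees = n_trees, importance = "permutation",
                        seed = sub_seed(seed, "rf_obs"))
  obs <- fit$variable.importance
  nullc <- local_seed(sub_seed(seed, "rf_null"), {
    cnt <- setNames(numeric(length(obs)), names(obs))
    for (b in seq_len(n_perm)) {
      dfp <- df
      dfp$.y <- sample(y)
      fp <- ranger::ranger(dependent.variable.name = ".y", data = dfp,
                           num.trees = n_trees, importance = "permutation",
                           seed = sub_seed(seed, paste0("rf_b", b)))
      cnt <- cnt + (fp$variable.importance >= obs)
    }
    cnt
  })
  data.frame(variable = names(obs), importance = unname(obs),
             p = unname((1 + nullc) / (1 + n_perm)),
             stringsAsFactors = FALSE)
}
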