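#' @importFrom stats cor cov lm pchisq prcomp pt quantile rnorm runif
#' @importFrom stats rmultinom sd coef kruskal.test p.adjust rgamma
#' @importFrom stats setNames cmdscale as.dist
#' @importFrom utils combn head read.table write.table packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local, explicit RNG seed
#'
#' All randomness in the package flows through this helper so that no
#' function touches the caller's global RNG state. A `NULL` seed is rejected
#' for operations that are defined to be reproducible.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

## derive a stream-specific 31-bit sub-seed from a master seed
sub_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.integer(seed) * 10007L + as.integer(h %% 100003L)) %% 2147483647L
}

stop_if_not_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    stop(sprintf("'%s' must be a positive integer count", name), call. = FALSE)
  invisible(as.integer(x))
}

## Ezekiel adjusted R-squared for an OLS fit with p predictors at n points
adj_r2 <- function(r2, n, p) {
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

## R-squared of lm fit of y on columns of X (X may have zero columns)
ols_r2 <- function(y, X) {
  if (is.null(X) || NCOL(X) == 0L) return(0)
  fit <- stats::lm.fit(cbind(1, as.matrix(X)), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}
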