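#' Min-max standardize a function matrix to [0, 1]
#'
#' Each function column is multiplied by its direction (+1 for functions
#' where larger is better, -1 for inverted functions) and then rescaled by
#' `(x - min) / (max - min)`. Constant columns carry no ranking information
#' and are mapped to 0.5 with a warning.
#'
#' @param fm Numeric plots x functions matrix.
#' @param direction Named vector of +1/-1 per function, or a single value
#'   recycled; defaults to +1 everywhere.
#' @return Matrix of the same shape with values in [0, 1].
#' @export
standardize_functions <- function(fm, direction = 1) {
  fm <- as.matrix(fm)
  if (nrow(fm) < 2) stop("need at least 2 plots to min-max standardize")
  if (any(!is.finite(fm))) stop("function matrix must be finite")
  dir <- expand_direction(direction, colnames(fm), ncol(fm))
  out <- fm
  constant <- logical(ncol(fm))
  for (j in seq_len(ncol(fm))) {
    x <- fm[, j] * dir[j]
    rng <- range(x)
    if (rng[1] == rng[2]) {
      constant[j] <- TRUE
      out[, j] <- 0.5
    } else {
      out[, j] <- (x - rng[1]) / (rng[2] - rng[1])
    }
  }
  if (any(constant))
    warning(sprintf("constant function column(s) mapped to 0.5: %s",
                    paste(colnames(fm)[constant], collapse = ", ")))
  out
}

expand_direction <- function(direction, ids, p) {
  if (length(direction) == 1L) direction <- rep(direction, p)
  if (!is.null(names(direction)) && !is.null(ids)) {
    if (!all(ids %in% names(direction)))
      stop("direction map is missing some function IDs")
    direction <- direction[ids]
  }
  if (length(direction) != p || !all(direction %in% c(-1, 1)))
    stop("direction must be +1/-1 per function")
  direction
}

#' Average multifunctionality index (avgFunc)
#'
#' Arithmetic mean of the 0-1 standardized functions per plot.
#'
#' @param std Standardized plots x functions matrix (values in [0, 1]).
#' @return Named numeric vector, one value per plot.
#' @export
avg_multifunctionality <- function(std) {
  std <- as.matrix(std)
  if (any(std < -1e-9 | std > 1 + 1e-9))
    stop("input must be standardized to [0, 1]; see standardize_functions()")
  rowMeans(std)
}

#' Multithreshold multifunctionality counts
#'
#' For each function the reference maximum is the mean of its `top_n`
#' largest direction-adjusted observed values; `mf_counts[t]` is the number
#' of functions in a plot at or above `t`% of that reference.
#'
#' @param fm Raw plots x functions matrix (direction-adjusted internally).
#' @param thresholds Percent thresholds in (0, 100]; default 20/40/60/80.
#' @param top_n Number of top values averaged into the reference maximum.
#' @param direction As in [standardize_functions()].
#' @return Integer matrix plots x thresholds (columns named `MF-20` etc.).
#' @export
threshold_multifunctionality <- function(fm, thresholds = c(20, 40, 60, 80),
                                         top_n = 2, direction = 1) {
  fm <- as.matrix(fm)
  if (nrow(fm) < 2) stop("need at least 2 plots")
  if (any(thresholds <= 0 | thresholds > 100))
    stop("thresholds must lie in (0, 100]")
  dir <- expand_direction(direction, colnames(fm), ncol(fm))
  adj <- sweep(fm, 2, dir, `*`)
  refmax <- apply(adj, 2, function(x)
    mean(sort(x, decreasing = TRUE)[seq_len(min(top_n, length(x)))]))
  out <- sapply(thresholds, function(t)
    rowSums(sweep(adj, 2, (t / 100) * refmax, `>=`)))
  out <- matrix(as.integer(out), nrow = nrow(fm),
                dimnames = list(rownames(fm), paste0("MF-", thresholds)))
  out
}

#' Full EMF profile per plot
#'
#' Convenience wrapper returning avgFunc, multithreshold counts and
#' per-category means of the standardized functions.
#'
#' @inheritParams threshold_multifunctionality
#' @param category Named map function id -> category label.
#' @return data.frame with plot_id, avgFunc, MF-t columns and one
#'   `cat_<label>` column per category.
#' @export
emf_profile <- function(fm, category, thresholds = c(20, 40, 60, 80),
                        top_n = 2, direction = 1) {
  std <- standardize_functions(fm, direction)
  av <- avg_multifunctionality(std)
  mf <- threshold_multifunctionality(fm, thresholds, top_n, direction)
  cats <- unique(category[colnames(fm)])
  cmeans <- sapply(cats, function(cc)
    rowMeans(std[, category[colnames(fm)] == cc, drop = FALSE]))
  colnames(cmeans) <- paste0("cat_", cats)
  data.frame(plot_id = rownames(fm), avgFunc = av, mf, cmeans,
             check.names = FALSE, row.names = NULL)
}

#' Annualised effect size of a disturbance between two time points
#'
#' `effect = (mean(Y_i) - mean(Y_j)) / ((i - j) * mean(Y_j))`: the relative
#' change per year between the group sampled at year `j` and the group
#' sampled at year `i`. For installation effects `i = 1, j = 0` (first year
#' after installation vs. undisturbed baseline); for running effects
#' `i = 6, j = 1`. The 95% confidence interval is a percentile bootstrap,
#' resampling plots within each year independently.
#'
#' @param values_i,values_j Per-plot values for years `i` and `j`.
#' @param i,j Years since disturbance (`i > j`).
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @return List with `effect`, `ci_low`, `ci_high`, `n_boot`, `seed`,
#'   `i`, `j`.
#' @export
annual_effect_size <- function(values_i, values_j, i, j, n_boot = 2000,
                               seed = 1) {
  stopifnot(is.numeric(values_i), is.numeric(values_j), i > j)
  mj <- mean(values_j)
  if (mj == 0) stop("mean of the reference year is zero; effect undefined")
  eff <- (mean(values_i) - mj) / ((i - j) * mj)
  boots <- local_seed(sub_seed(seed, "effect_boot"), {
    vapply(seq_len(n_boot), function(b) {
      bi <- sample(values_i, replace = TRUE)
      bj <- sample(values_j, replace = TRUE)
      mbj <- mean(bj)
      if (mbj == 0) return(NA_real_)
      (mean(bi) - mbj) / ((i - j) * mbj)
    }, numeric(1))
  })
  ci <- quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(effect = eff, ci_low = ci[1], ci_high = ci[2],
       n_boot = n_boot, seed = seed, i = i, j = j)
}

#' Kruskal-Wallis comparison of a variable across groups
#'
#' Rank-based H with tie correction and a chi-square p-value on k - 1
#' degrees of freedom. If every observation is identical the statistic is 0
#' and p = 1 (the tie correction is degenerate there).
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @return List with `H`, `p`, `df`.
#' @export
compare_groups <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("need at least 2 observations per group")
  if (length(unique(values)) == 1L)
    return(list(H = 0, p = 1, df = nlevels(groups) - 1L))
  kt <- kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}
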