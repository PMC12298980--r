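# Independent oracles used to check the package implementations.
# These deliberately re-derive each quantity by the most literal route
# (edge enumeration, exhaustive search, direct formulas) and never call
# the functions they are checking.

# Faith's PD by explicit root-to-tip edge enumeration
oracle_faith_pd <- function(tree, tips) {
  if (!length(tips)) return(0)
  root <- length(tree$tip.label) + 1L
  used <- integer(0)
  for (tp in tips) {
    node <- match(tp, tree$tip.label)
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      used <- union(used, e)
      node <- tree$edge[e, 1]
    }
  }
  sum(tree$edge.length[used])
}

# IndVal statistic for one labeled assignment, written longhand
oracle_indval_stat <- function(counts, assign_groups) {
  rel <- sweep(counts, 2, colSums(counts), `/`)
  gs <- unique(assign_groups)
  apply(rel, 1, function(x) {
    mg <- sapply(gs, function(g) mean(x[assign_groups == g]))
    if (sum(mg) == 0) return(0)
    A <- mg / sum(mg)
    B <- sapply(gs, function(g) mean(x[assign_groups == g] > 0))
    max(sqrt(A * B))
  })
}

# all distinct labeled assignments of samples 1..n into groups of set sizes
oracle_all_assignments <- function(sizes) {
  out <- list()
  rec <- function(avail, acc, rem) {
    if (length(rem) == 0L) {
      out[[length(out) + 1]] <<- acc[order(as.integer(names(acc)))]
      return(invisible())
    }
    for (cmb in utils::combn(avail, rem[[1]], simplify = FALSE))
      rec(setdiff(avail, cmb),
          c(acc, setNames(rep(names(rem)[1], length(cmb)), cmb)),
          rem[-1])
  }
  rec(seq_len(sum(unlist(sizes))), setNames(character(0), character(0)),
      as.list(sizes))
  out
}

# exhaustive permutation p for every taxon of a tiny table
oracle_indval_exhaustive_p <- function(counts, groups) {
  groups <- as.factor(groups)
  obs <- oracle_indval_stat(counts, as.character(groups))
  sizes <- setNames(as.integer(table(groups)), levels(groups))
  assigns <- oracle_all_assignments(sizes)
  stat_mat <- sapply(assigns, function(a)
    oracle_indval_stat(counts, unname(a)))
  if (is.null(dim(stat_mat))) stat_mat <- matrix(stat_mat, nrow = 1)
  rowMeans(stat_mat >= obs - 1e-12)
}

# Newman-Girvan modularity computed from first principles
oracle_modularity <- function(edges, membership) {
  m <- nrow(edges)
  if (m == 0) return(0)
  deg <- table(factor(c(edges$from, edges$to), levels = names(membership)))
  q <- 0
  for (cm in unique(membership)) {
    nodes <- names(membership)[membership == cm]
    e_in <- sum(edges$from %in% nodes & edges$to %in% nodes)
    d_in <- sum(deg[nodes])
    q <- q + e_in / m - (d_in / (2 * m))^2
  }
  q
}

# construct an n x k data matrix whose sample covariance is exactly S
exact_cov_data <- function(S, n, seed = 1) {
  k <- ncol(S)
  withr::with_seed(seed, {
    X <- scale(matrix(rnorm(n * k), n, k), center = TRUE, scale = FALSE)
    Q <- qr.Q(qr(X))
    Y <- Q %*% chol(S) * sqrt(n - 1)
    colnames(Y) <- colnames(S)
    Y
  })
}
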