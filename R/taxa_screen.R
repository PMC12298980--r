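#' Prevalence/count filter for ASV tables
#'
#' Retains taxa observed with at least `min_count` reads in at least
#' `ceiling(prevalence * n_samples)` samples (default: >= 4 counts in >= 20%
#' of samples). `mode = "strict"` instead requires >= `min_count` in every
#' sample, the literal reading of the rule, which discards nearly all taxa
#' and is provided for comparison only.
#'
#' @param ct Taxa x samples integer count matrix.
#' @param prevalence Fraction of samples in (0, 1] (default 0.20).
#' @param min_count Minimum per-sample count (default 4).
#' @param mode `"prevalence"` (default) or `"strict"`.
#' @return The filtered count matrix (same samples, subset of taxa).
#' @export
filter_asvs <- function(ct, prevalence = 0.20, min_count = 4,
                        mode = c("prevalence", "strict")) {
  mode <- match.arg(mode)
  ct <- as.matrix(ct)
  if (any(ct != floor(ct)) || any(ct < 0)) stop("counts must be non-negative integers")
  if (prevalence <= 0 || prevalence > 1) stop("prevalence must be in (0, 1]")
  keep <- if (mode == "prevalence") {
    rowSums(ct >= min_count) >= ceiling(prevalence * ncol(ct))
  } else {
    rowSums(ct >= min_count) == ncol(ct)
  }
  ct[keep, , drop = FALSE]
}

#' Classify taxa as rare / intermediate / abundant
#'
#' Overall relative abundance is the taxon's total count over the grand
#' total; taxa strictly below `rare_below` (0.01%) are rare and strictly
#' above `abundant_above` (0.1%) are abundant, boundaries exclusive.
#'
#' @param ct Taxa x samples count matrix with positive grand total.
#' @param rare_below,abundant_above Fractional thresholds (defaults 1e-4
#'   and 1e-3).
#' @return data.frame: taxon_id, overall_rel_abund, class.
#' @export
classify_abundance <- function(ct, rare_below = 1e-4, abundant_above = 1e-3) {
  ct <- as.matrix(ct)
  total <- sum(ct)
  if (total <= 0) stop("total count must be positive")
  rel <- rowSums(ct) / total
  cls <- ifelse(rel < rare_below, "rare",
                ifelse(rel > abundant_above, "abundant", "intermediate"))
  data.frame(taxon_id = rownames(ct), overall_rel_abund = unname(rel),
             class = unname(cls), stringsAsFactors = FALSE)
}

## all distinct assignments of n samples into labeled groups of given sizes
enumerate_assignments <- function(sizes) {
  n <- sum(sizes)
  rec <- function(avail, sizes) {
    if (length(sizes) == 1L) return(list(list(avail)))
    first <- utils::combn(avail, sizes[1], simplify = FALSE)
    out <- list()
    for (f in first) {
      rest <- rec(setdiff(avail, f), sizes[-1])
      out <- c(out, lapply(rest, function(r) c(list(f), r)))
    }
    out
  }
  rec(seq_len(n), sizes)
}

indval_stats <- function(rel, pres, gmat_mean) {
  ## rel, pres: taxa x samples; gmat_mean: samples x G with 1/n_g weights
  mg <- rel %*% gmat_mean                # taxa x G mean abundance
  tot <- rowSums(mg)
  A <- mg / ifelse(tot == 0, 1, tot)
  B <- pres %*% gmat_mean
  sq <- sqrt(A * B)
  sq[tot == 0, ] <- 0
  list(stat = apply(sq, 1, max), best = apply(sq, 1, which.max), A = A, B = B)
}

#' Indicator species analysis (IndVal) with permutation test
#'
#' For taxon k and group g, specificity `A = mean abundance of k in g /
#' sum over groups of mean abundances` and fidelity `B = fraction of g's
#' samples where k is present`; `IndVal_k = max_g sqrt(A * B)`. Significance
#' is assessed by permuting group labels; `p = (1 + #permuted >= observed) /
#' (1 + n_perm)`, or by exhaustive enumeration of all distinct label
#' assignments when `n_perm = "exhaustive"`. Computed on per-sample relative
#' abundances to remove depth artifacts. The `is_indicator` flag uses
#' Benjamini-Hochberg adjusted p < `alpha` so that the expected false
#' discovery proportion among flagged taxa is controlled at `alpha`.
#'
#' @param ct Taxa x samples count (or relative abundance) matrix.
#' @param groups Group label per sample (>= 2 groups, all non-empty).
#' @param n_perm Number of label permutations (default 999) or
#'   `"exhaustive"`.
#' @param seed Integer seed.
#' @param alpha FDR level for the indicator flag (default 0.10, the
#'   conventional exploratory screening level).
#' @return data.frame: taxon_id, best_group, A, B, indval, p_perm, p_adj,
#'   is_indicator; attributes `n_perm` and `seed`.
#' @export
indval <- function(ct, groups, n_perm = 999, seed = 1, alpha = 0.10) {
  ct <- as.matrix(ct)
  groups <- as.factor(groups)
  if (length(groups) != ncol(ct)) stop("one group label per sample required")
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) == 0)) stop("every group needs at least one sample")
  cs <- colSums(ct)
  if (any(cs == 0)) stop("empty samples are not allowed")
  rel <- sweep(ct, 2, cs, `/`)
  pres <- (ct > 0) * 1
  G <- nlevels(groups)
  W <- vapply(levels(groups), function(g) (groups == g) / sum(groups == g),
              numeric(ncol(ct)))
  obs <- indval_stats(rel, pres, W)

  exhaustive <- identical(n_perm, "exhaustive")
  if (exhaustive) {
    sizes <- as.integer(table(groups))
    asn <- enumerate_assignments(sizes)
    ge <- vapply(asn, function(a) {
      Wp <- matrix(0, ncol(ct), G)
      for (g in seq_len(G)) Wp[a[[g]], g] <- 1 / sizes[g]
      indval_stats(rel, pres, Wp)$stat >= obs$stat - 1e-12
    }, logical(nrow(ct)))
    ge <- if (is.matrix(ge)) rowSums(ge) else sum(ge)
    p <- ge / length(asn)
    n_perm_used <- length(asn)
  } else {
    stop_if_not_count(n_perm, "n_perm")
    ge <- local_seed(sub_seed(seed, "indval"), {
      count <- numeric(nrow(ct))
      for (b in seq_len(n_perm)) {
        idx <- sample(ncol(ct))
        st <- indval_stats(rel, pres, W[idx, , drop = FALSE])$stat
        count <- count + (st >= obs$stat - 1e-12)
      }
      count
    })
    p <- (1 + ge) / (1 + n_perm)
    n_perm_used <- n_perm
  }
  iA <- cbind(seq_len(nrow(ct)), obs$best)
  out <- data.frame(
    taxon_id = rownames(ct) %||% as.character(seq_len(nrow(ct))),
    best_group = levels(groups)[obs$best],
    A = obs$A[iA], B = obs$B[iA],
    indval = obs$stat, p_perm = p,
    p_adj = p.adjust(p, "BH"),
    stringsAsFactors = FALSE
  )
  out$is_indicator <- out$p_adj < alpha
  attr(out, "n_perm") <- n_perm_used
  attr(out, "seed") <- seed
  out
}

#' Build a co-occurrence network from a community table
#'
#' Spearman correlations between taxa on per-sample relative abundances;
#' an edge joins two taxa when `|rho| >= r_min` and the Benjamini-Hochberg
#' adjusted p-value (t approximation on n - 2 df) is `<= p_max`. Edge sign
#' is kept as an attribute. Constant taxa have undefined correlations and
#' are left isolated with a warning.
#'
#' @param ct Taxa x samples count matrix (>= 5 samples).
#' @param method Correlation method (default `"spearman"`).
#' @param r_min Minimum absolute correlation (default 0.6).
#' @param p_max Maximum BH-adjusted p (default 0.05).
#' @return An undirected [igraph] graph whose vertices are the taxa; edges
#'   carry `rho` and `sign` attributes.
#' @export
build_network <- function(ct, method = "spearman", r_min = 0.6, p_max = 0.05) {
  ct <- as.matrix(ct)
  n <- ncol(ct)
  if (n < 5) stop("need at least 5 samples")
  rel <- sweep(ct, 2, pmax(colSums(ct), 1), `/`)
  sds <- apply(rel, 1, sd)
  if (any(sds == 0))
    warning(sprintf("%d constant taxa left isolated", sum(sds == 0)))
  r <- suppressWarnings(cor(t(rel), method = method))
  r[!is.finite(r)] <- 0
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
  pmat <- 2 * pt(-abs(tstat), n - 2)
  ut <- upper.tri(r)
  padj <- pmat
  padj[ut] <- p.adjust(pmat[ut], "BH")
  sel <- which(ut & abs(r) >= r_min & padj <= p_max, arr.ind = TRUE)
  taxa <- rownames(ct) %||% as.character(seq_len(nrow(ct)))
  edges <- data.frame(from = taxa[sel[, 1]], to = taxa[sel[, 2]],
                      rho = r[sel], sign = ifelse(r[sel] > 0, "+", "-"),
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = taxa))
}

#' Detect modules by deterministic greedy modularity maximization
#'
#' Uses igraph's greedy modularity agglomeration (`cluster_fast_greedy`),
#' which is deterministic for a fixed vertex order; isolated vertices end
#' up in singleton modules.
#'
#' @param graph Undirected igraph graph.
#' @return Named integer vector: module id per vertex.
#' @export
detect_modules <- function(graph) {
  vn <- igraph::V(graph)$name
  if (igraph::ecount(graph) == 0)
    return(setNames(seq_len(igraph::vcount(graph)), vn))
  cm <- igraph::cluster_fast_greedy(graph)
  ## pick the dendrogram cut maximizing modularity; on numerical ties
  ## (within 1e-10) prefer fewer modules, so e.g. a single clique is one
  ## module rather than an arbitrary near-zero split
  n <- igraph::vcount(graph)
  qs <- vapply(seq_len(n), function(k)
    igraph::modularity(graph, igraph::cut_at(cm, no = k)), numeric(1))
  k_best <- which(qs >= max(qs) - 1e-10)[1]
  m <- igraph::cut_at(cm, no = k_best)
  names(m) <- vn
  ## isolated vertices always get singleton modules
  deg <- igraph::degree(graph)
  iso <- which(deg == 0)
  if (length(iso))
    m[iso] <- max(m) + seq_along(iso)
  setNames(as.integer(m), vn)
}

#' Within-module degree (Zi) and participation coefficient (Pi)
#'
#' `Zi = (k_within - mean(k_within in module)) / sd(k_within in module)`
#' with the convention Zi = 0 when the module's sd is 0;
#' `Pi = 1 - sum_s (k_is / k_i)^2` over modules s, with Pi = 0 for isolated
#' nodes. A node is a network keystone when Zi > 2.5 or Pi > 0.62 (rule
#' `"or"`, the default permissive reading; `"and"` requires both).
#'
#' @param graph Undirected igraph graph.
#' @param modules Named module assignment covering all vertices (from
#'   [detect_modules()]).
#' @param zi_cut,pi_cut Keystone thresholds (defaults 2.5 and 0.62).
#' @param rule `"or"` or `"and"`.
#' @return data.frame: taxon_id, module_id, zi, pi, is_keystone.
#' @export
zi_pi <- function(graph, modules, zi_cut = 2.5, pi_cut = 0.62,
                  rule = c("or", "and")) {
  rule <- match.arg(rule)
  vn <- igraph::V(graph)$name
  if (!all(vn %in% names(modules))) stop("modules must cover all vertices")
  mod <- modules[vn]
  adj <- igraph::as_adjacency_matrix(graph, sparse = FALSE)
  adj <- (adj > 0) * 1
  k <- rowSums(adj)
  mods <- sort(unique(mod))
  M <- vapply(mods, function(m) (mod == m) * 1, numeric(length(vn)))
  kis <- adj %*% M                                   # node x module degree
  k_within <- kis[cbind(seq_along(vn), match(mod, mods))]
  zi <- numeric(length(vn))
  for (m in mods) {
    idx <- mod == m
    s <- sd(k_within[idx])
    zi[idx] <- if (sum(idx) < 2 || is.na(s) || s == 0) 0
               else (k_within[idx] - mean(k_within[idx])) / s
  }
  pi <- ifelse(k == 0, 0, 1 - rowSums(sweep(kis, 1, pmax(k, 1), `/`)^2))
  keystone <- if (rule == "or") zi > zi_cut | pi > pi_cut
              else zi > zi_cut & pi > pi_cut
  data.frame(taxon_id = vn, module_id = unname(mod), zi = unname(zi),
             pi = unname(pi), is_keystone = unname(keystone),
             stringsAsFactors = FALSE)
}

## z-score columns, drop constants, PCA with deterministic sign anchoring
pca_anchored <- function(mat, anchor = NULL) {
  mat <- as.matrix(mat)
  sds <- apply(mat, 2, sd)
  if (any(sds == 0)) {
    warning(sprintf("constant column(s) dropped: %s",
                    paste(colnames(mat)[sds == 0], collapse = ", ")))
    mat <- mat[, sds > 0, drop = FALSE]
  }
  if (ncol(mat) < 2) stop("need at least 2 non-constant variables")
  z <- scale(mat)
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  for (j in seq_len(ncol(pc$rotation))) {
    flip <- if (!is.null(anchor) && anchor %in% rownames(pc$rotation)) {
      pc$rotation[anchor, j] < 0
    } else {
      pc$rotation[which.max(abs(pc$rotation[, j])), j] < 0
    }
    if (flip) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  list(scores = pc$x, loadings = pc$rotation,
       var_explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' PCA composite of indicator-taxon relative abundances
#'
#' Restricts the table to the given indicator taxa, converts to per-sample
#' relative abundances, z-scores each taxon and runs a PCA. Component signs
#' are fixed so that each component's largest-magnitude loading is positive.
#'
#' @param ct Taxa x samples count matrix.
#' @param indicator_taxa Character vector of >= 2 taxon IDs present in `ct`.
#' @return List: `scores` (samples x components), `loadings`,
#'   `var_explained`.
#' @export
indicator_composite <- function(ct, indicator_taxa) {
  ct <- as.matrix(ct)
  indicator_taxa <- intersect(indicator_taxa, rownames(ct))
  if (length(indicator_taxa) < 2) stop("need at least 2 indicator taxa")
  rel <- sweep(ct, 2, pmax(colSums(ct), 1), `/`)
  pca_anchored(t(rel[indicator_taxa, , drop = FALSE]))
}
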