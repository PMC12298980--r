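#' Taxon richness per sample
#'
#' @param ct Taxa x samples count matrix (non-negative).
#' @return Named integer vector of per-sample counts of taxa with count > 0.
#' @export
richness <- function(ct) {
  ct <- as.matrix(ct)
  if (any(ct < 0)) stop("counts must be non-negative")
  colSums(ct > 0)
}

#' Faith's phylogenetic diversity per sample
#'
#' Sum of branch lengths of the minimal subtree spanning the taxa present
#' in a sample. The classic definition including the path to the root is
#' the default; `include_root = FALSE` instead spans only the tips' most
#' recent common ancestor. Computed by enumerating, for every present tip,
#' the edges on its path to the root and summing the union once; samples
#' with no taxa get PD 0. Works for multifurcating (e.g. star) trees.
#'
#' @param ct Taxa x samples count matrix; rownames are tip labels.
#' @param tree An [ape::phylo] tree covering every present taxon.
#' @param include_root Include the path to the root (default `TRUE`).
#' @return Named numeric vector of PD per sample.
#' @export
faith_pd <- function(ct, tree, include_root = TRUE) {
  ct <- as.matrix(ct)
  present <- rownames(ct)[rowSums(ct > 0) > 0]
  missing <- setdiff(present, tree$tip.label)
  if (length(missing))
    stop(sprintf("taxa present but absent from tree: %s",
                 paste(head(missing, 5), collapse = ", ")))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent_edge <- integer(max(tree$edge))        # edge index leading into node
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  ## per-tip path to root, as edge indices
  tip_path <- lapply(seq_len(ntip), function(tp) {
    path <- integer(0)
    node <- tp
    while (node != root) {
      e <- parent_edge[node]
      path <- c(path, e)
      node <- tree$edge[e, 1]
    }
    path
  })
  names(tip_path) <- tree$tip.label
  vapply(seq_len(ncol(ct)), function(s) {
    tips <- rownames(ct)[ct[, s] > 0]
    if (!length(tips)) return(0)
    paths <- tip_path[tips]
    edges <- unique(unlist(paths))
    if (!include_root && length(tips) >= 1) {
      ## drop edges above the tips' MRCA: those common to every tip path
      shared <- Reduce(intersect, paths)
      edges <- setdiff(edges, shared)
    }
    sum(tree$edge.length[edges])
  }, numeric(1)) |> setNames(colnames(ct))
}

#' Gower distance between species from a trait table
#'
#' For each pair, the mean over traits of `|x - y| / range` for quantitative
#' traits and a 0/1 mismatch for categorical traits; trait values missing in
#' either species are skipped and the remaining traits re-weighted.
#' Zero-range traits are uninformative and are excluded with a warning.
#'
#' @param traits data.frame, one row per species, rownames (or a `species`
#'   column) giving species IDs; numeric and factor/character columns.
#' @return Symmetric species x species distance matrix with values in
#'   [0, 1] and zero diagonal.
#' @export
gower_distance <- function(traits) {
  traits <- as.data.frame(traits)
  if ("species" %in% names(traits)) {
    rownames(traits) <- traits$species
    traits$species <- NULL
  }
  if (ncol(traits) < 1) stop("need at least one trait")
  n <- nrow(traits)
  ids <- rownames(traits) %||% as.character(seq_len(n))
  num <- 0
  den <- 0
  kept <- 0L
  for (j in seq_len(ncol(traits))) {
    x <- traits[[j]]
    if (is.numeric(x)) {
      rng <- diff(range(x, na.rm = TRUE))
      if (!is.finite(rng)) stop(sprintf("trait '%s' has no finite range", names(traits)[j]))
      if (rng == 0) {
        warning(sprintf("zero-range trait '%s' excluded", names(traits)[j]))
        next
      }
      d <- abs(outer(x, x, `-`)) / rng
    } else {
      x <- as.character(x)
      d <- outer(x, x, `!=`) * 1
    }
    ok <- (!is.na(outer(x, x, function(a, b) a)) &
             !is.na(outer(x, x, function(a, b) b))) * 1
    d[ok == 0] <- 0
    num <- num + d
    den <- den + ok
    kept <- kept + 1L
  }
  if (kept == 0L) stop("no usable traits remain")
  if (any(den == 0)) stop("some species pairs share no observed trait")
  D <- num / den
  diag(D) <- 0
  dimnames(D) <- list(ids, ids)
  D
}

#' Functional dispersion (FDis) per sample
#'
#' Species are embedded by principal-coordinates analysis of the supplied
#' distance matrix (axes with negative eigenvalues truncated); FDis is the
#' abundance-weighted mean Euclidean distance of the present species to the
#' abundance-weighted community centroid. Samples with at most one present
#' species have FDis 0.
#'
#' @param ct Species x samples abundance matrix.
#' @param dist Symmetric species distance matrix covering all present
#'   species (e.g. from [gower_distance()]).
#' @return Named numeric vector of FDis per sample.
#' @export
functional_dispersion <- function(ct, dist) {
  ct <- as.matrix(ct)
  dist <- as.matrix(dist)
  sp <- rownames(ct)
  miss <- setdiff(sp[rowSums(ct > 0) > 0], rownames(dist))
  if (length(miss))
    stop(sprintf("distance matrix missing species: %s",
                 paste(head(miss, 5), collapse = ", ")))
  dist <- dist[sp, sp, drop = FALSE]
  n <- nrow(dist)
  coords <- if (n >= 2) {
    ## negative PCoA eigenvalues are truncated by design (warning silenced)
    pco <- suppressWarnings(cmdscale(as.dist(dist), k = max(1, n - 1), eig = TRUE))
    keep <- pco$eig > sqrt(.Machine$double.eps)
    if (!any(keep)) matrix(0, n, 1, dimnames = list(sp, NULL))
    else {
      X <- pco$points[, seq_len(sum(keep[seq_len(ncol(pco$points))])), drop = FALSE]
      rownames(X) <- sp
      X
    }
  } else matrix(0, n, 1, dimnames = list(sp, NULL))
  vapply(seq_len(ncol(ct)), function(s) {
    a <- ct[, s]
    pres <- a > 0
    if (sum(pres) <= 1) return(0)
    w <- a[pres] / sum(a[pres])
    X <- coords[pres, , drop = FALSE]
    centroid <- colSums(X * w)
    dd <- sqrt(rowSums(sweep(X, 2, centroid)^2))
    sum(w * dd)
  }, numeric(1)) |> setNames(colnames(ct))
}

#' Functional-group (guild) richness per sample
#'
#' Number of distinct functional groups (fungal guilds or prokaryotic
#' pathways) represented among the taxa present in a sample, counting only
#' assignments whose confidence label is in `accept`.
#'
#' @param ct Taxa x samples count matrix.
#' @param guild_map data.frame with columns `taxon_id`, `guild` and
#'   optionally `guild_confidence`.
#' @param accept Confidence labels to count (default the highly
#'   probable/probable tiers).
#' @return Named integer vector per sample.
#' @export
guild_richness <- function(ct, guild_map,
                           accept = c("Highly Probable", "Probable")) {
  ct <- as.matrix(ct)
  gm <- guild_map
  if (!is.null(gm$guild_confidence)) gm <- gm[gm$guild_confidence %in% accept, ]
  g <- setNames(gm$guild, gm$taxon_id)
  vapply(seq_len(ncol(ct)), function(s) {
    pres <- rownames(ct)[ct[, s] > 0]
    length(unique(stats::na.omit(g[pres])))
  }, integer(1)) |> setNames(colnames(ct))
}

#' Between-sample distance matrices for communities or functions
#'
#' Bray-Curtis on per-sample relative abundances for community tables;
#' Euclidean on z-scored columns for function matrices.
#'
#' @param x Taxa x samples counts (`metric = "bray-curtis"`) or samples x
#'   variables matrix (`metric = "euclidean"`).
#' @param metric `"bray-curtis"` or `"euclidean"`.
#' @return A [stats::dist] object.
#' @export
beta_distance <- function(x, metric = c("bray-curtis", "euclidean")) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  if (metric == "bray-curtis") {
    if (ncol(x) < 2) stop("need at least 2 samples")
    if (any(colSums(x) == 0)) stop("Bray-Curtis undefined for empty samples")
    rel <- t(sweep(x, 2, colSums(x), `/`))
    vegan::vegdist(rel, method = "bray")
  } else {
    if (nrow(x) < 2) stop("need at least 2 samples")
    z <- scale(x)
    z[, attr(z, "scaled:scale") == 0] <- 0
    stats::dist(z)
  }
}

#' Alpha-diversity profile for one domain
#'
#' @param ct Taxa x samples counts.
#' @param tree Optional phylogeny for Faith's PD.
#' @param traits Optional trait table for FDis (via Gower distance).
#' @param guild_map Optional taxon -> guild map for guild richness.
#' @return data.frame with sample_id, richness and any of faith_pd, fdis,
#'   guild_richness that the inputs support.
#' @export
diversity_profile <- function(ct, tree = NULL, traits = NULL,
                              guild_map = NULL) {
  out <- data.frame(sample_id = colnames(ct), richness = unname(richness(ct)),
                    stringsAsFactors = FALSE)
  if (!is.null(tree)) out$faith_pd <- unname(faith_pd(ct, tree))
  if (!is.null(traits))
    out$fdis <- unname(functional_dispersion(ct, gower_distance(traits)))
  if (!is.null(guild_map))
    out$guild_richness <- unname(guild_richness(ct, guild_map))
  out
}
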