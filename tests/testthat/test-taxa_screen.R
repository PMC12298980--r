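make_counts <- function(mat, taxa = NULL, samples = NULL) {
  taxa <- taxa %||% paste0("t", seq_len(nrow(mat)))
  samples <- samples %||% paste0("s", seq_len(ncol(mat)))
  dimnames(mat) <- list(taxa, samples)
  mat
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the prevalence/count filter implements the stated rule", {
  ct <- matrix(0L, 3, 18)
  ct[1, 1:4] <- 4L        # 4 counts in 4 of 18 samples: 4 >= ceiling(3.6)
  ct[2, 1] <- 50L         # present in 1 sample only
  ct[3, ] <- 3L           # never reaches 4 counts
  ct <- make_counts(ct)
  kept <- filter_asvs(ct)
  expect_identical(rownames(kept), "t1")
  # strict mode requires >= 4 everywhere
  expect_identical(nrow(filter_asvs(ct, mode = "strict")), 0L)
  ct4 <- make_counts(matrix(4L, 1, 18))
  expect_identical(nrow(filter_asvs(ct4, mode = "strict")), 1L)
  expect_error(filter_asvs(ct, prevalence = 0), "prevalence")
  expect_error(filter_asvs(ct * 0.5), "integers")
})

test_that("abundance classes use exclusive thresholds on overall fractions", {
  ct <- make_counts(matrix(c(5, 150, 10, 99835), 4, 1))
  cls <- classify_abundance(ct)
  expect_equal(cls$class[cls$taxon_id == "t1"], "rare")        # 0.005%
  expect_equal(cls$class[cls$taxon_id == "t2"], "abundant")    # 0.15%
  expect_equal(cls$class[cls$taxon_id == "t3"], "intermediate") # exactly 0.01%
  expect_setequal(unique(cls$class), c("rare", "abundant", "intermediate"))
})

test_that("IndVal reproduces hand-computed specificity/fidelity products", {
  grp <- rep(c("g1", "g2"), each = 3)
  perfect <- make_counts(rbind(c(5, 8, 3, 0, 0, 0), c(2, 2, 2, 2, 2, 2)))
  iv <- indval(perfect, grp, n_perm = "exhaustive")
  expect_equal(iv$indval[1], 1, tolerance = 1e-10)
  expect_equal(iv$best_group[1], "g1")
  # equal relative abundance in 2 equal groups, present everywhere
  # (constant rows keep per-sample relative abundances identical)
  equalct <- make_counts(rbind(rep(2, 6), rep(3, 6)))
  ive <- indval(equalct, grp, n_perm = "exhaustive")
  expect_equal(ive$indval, rep(sqrt(0.5), 2), tolerance = 1e-10)
  expect_equal(ive$A, rep(0.5, 2), tolerance = 1e-12)
  expect_equal(ive$B, rep(1, 2))
  expect_true(all(abs(iv$indval^2 - iv$A * iv$B) < 1e-12))
  expect_error(indval(perfect, rep("g1", 6)), "2 groups")
})

test_that("exhaustive IndVal p-values match independent enumeration", {
  for (s in 1:5) {
    ct <- withr::with_seed(s, make_counts(matrix(rpois(4 * 6, 3) + 1L, 4, 6)))
    grp <- rep(c("g1", "g2"), each = 3)
    iv <- indval(ct, grp, n_perm = "exhaustive")
    expect_equal(attr(iv, "n_perm"), 20L)
    expect_equal(iv$p_perm, unname(oracle_indval_exhaustive_p(ct, grp)),
                 tolerance = 1e-12)
  }
  # three unequal groups
  ct <- withr::with_seed(9, make_counts(matrix(rpois(3 * 7, 2) + 1L, 3, 7)))
  grp <- c("a", "a", "b", "b", "c", "c", "c")
  iv <- indval(ct, grp, n_perm = "exhaustive")
  expect_equal(iv$p_perm, unname(oracle_indval_exhaustive_p(ct, grp)),
               tolerance = 1e-12)
})

test_that("IndVal is invariant to permuting samples within groups", {
  ct <- withr::with_seed(3, make_counts(matrix(rpois(6 * 9, 4) + 1L, 6, 9)))
  grp <- rep(c("a", "b", "c"), each = 3)
  iv1 <- indval(ct, grp, n_perm = "exhaustive")
  perm <- c(2, 3, 1, 6, 4, 5, 9, 7, 8)   # shuffles within each group
  iv2 <- indval(ct[, perm], grp, n_perm = "exhaustive")
  expect_equal(iv1$indval, iv2$indval, tolerance = 1e-12)
  expect_equal(iv1$p_perm, iv2$p_perm, tolerance = 1e-12)
  expect_equal(iv1$best_group, iv2$best_group)
})

test_that("co-occurrence edges capture perfect and anti-correlated pairs", {
  # constant column sums keep relative abundances monotone in the counts
  x <- pmin(withr::with_seed(5, rpois(12, 20)) + 1, 59)
  ct <- make_counts(rbind(x, x, 60 - x, 120 - x))
  g <- suppressWarnings(build_network(ct, r_min = 0.9))
  e <- igraph::as_data_frame(g)
  pair_pos <- e[(e$from == "t1" & e$to == "t2") | (e$from == "t2" & e$to == "t1"), ]
  expect_equal(nrow(pair_pos), 1L)
  expect_equal(pair_pos$rho, 1, tolerance = 1e-10)
  pair_neg <- e[(e$from == "t1" & e$to == "t3") | (e$from == "t3" & e$to == "t1"), ]
  expect_equal(pair_neg$sign, "-")
  expect_equal(pair_neg$rho, -1, tolerance = 1e-10)
  expect_error(build_network(ct[, 1:4]), "5 samples")
})

test_that("independent taxa produce almost no edges after BH adjustment", {
  ct <- withr::with_seed(21, make_counts(matrix(rpois(60 * 18, 30), 60, 18)))
  g <- suppressWarnings(build_network(ct))
  n_pairs <- choose(60, 2)
  expect_lt(igraph::ecount(g) / n_pairs, 0.01)
})

test_that("module detection recovers planted cliques deterministically", {
  cl <- function(nodes) t(utils::combn(nodes, 2))
  edges <- rbind(cl(paste0("a", 1:5)), cl(paste0("b", 1:5)),
                 c("a1", "b1"))
  g <- igraph::graph_from_data_frame(as.data.frame(edges), directed = FALSE)
  mod <- detect_modules(g)
  expect_equal(length(unique(mod)), 2L)
  expect_equal(length(unique(mod[paste0("a", 1:5)])), 1L)
  expect_equal(length(unique(mod[paste0("b", 1:5)])), 1L)
  # achieved modularity is at least that of the best bipartition
  ed <- igraph::as_data_frame(g)
  best <- -Inf
  nodes <- names(mod)
  for (m in 0:(2^(length(nodes) - 1) - 1)) {
    mem <- setNames(c(0, as.integer(intToBits(m))[1:(length(nodes) - 1)]), nodes)
    best <- max(best, oracle_modularity(ed, mem))
  }
  expect_gte(oracle_modularity(ed, mod) + 1e-12, best)

  single <- igraph::graph_from_data_frame(
    as.data.frame(cl(paste0("c", 1:4))), directed = FALSE)
  expect_equal(length(unique(detect_modules(single))), 1L)
  lonely <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(lonely)$name <- paste0("x", 1:3)
  expect_equal(unname(detect_modules(lonely)), 1:3)
})

test_that("Zi and Pi follow their formulas including degenerate conventions", {
  # node n0 with degree 4 split 2/2 across two foreign modules
  edges <- data.frame(
    from = c("n0", "n0", "n0", "n0", "m1", "m2", "k1", "k2"),
    to   = c("m1", "m2", "k1", "k2", "m2", "m3", "k3", "k3"))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  mods <- c(n0 = 1, m1 = 2, m2 = 2, m3 = 2, k1 = 3, k2 = 3, k3 = 3)
  zp <- zi_pi(g, mods)
  n0 <- zp[zp$taxon_id == "n0", ]
  expect_equal(n0$pi, 0.5, tolerance = 1e-10)   # 1 - (0.25 + 0.25)
  # all edges inside own module -> Pi = 0
  k3 <- zp[zp$taxon_id == "k3", ]
  expect_equal(k3$pi, 0, tolerance = 1e-12)
  # clique: every member shares the within-degree -> sd 0 -> Zi = 0
  cl4 <- igraph::graph_from_data_frame(
    as.data.frame(t(utils::combn(paste0("c", 1:4), 2))), directed = FALSE)
  zcl <- zi_pi(cl4, setNames(rep(1, 4), paste0("c", 1:4)))
  expect_true(all(zcl$zi == 0))
  expect_error(zi_pi(g, mods[-1]), "cover")
})

test_that("keystone status flips exactly at the Zi and Pi thresholds", {
  edges <- data.frame(from = c("a", "a", "a", "b"), to = c("b", "c", "d", "c"))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  mods <- c(a = 1, b = 1, c = 2, d = 2)
  zp <- zi_pi(g, mods)
  a <- zp[zp$taxon_id == "a", ]
  # move the cutoffs epsilon around the node's own values
  above <- zi_pi(g, mods, zi_cut = a$zi + 1e-6, pi_cut = a$pi + 1e-6)
  below <- zi_pi(g, mods, zi_cut = a$zi + 1e-6, pi_cut = a$pi - 1e-6)
  expect_false(above$is_keystone[above$taxon_id == "a"])
  expect_true(below$is_keystone[below$taxon_id == "a"])
  zlow <- zi_pi(g, mods, zi_cut = a$zi - 1e-6, pi_cut = a$pi + 1e-6)
  expect_true(zlow$is_keystone[zlow$taxon_id == "a"])
  both <- zi_pi(g, mods, zi_cut = a$zi - 1e-6, pi_cut = a$pi + 1e-6, rule = "and")
  expect_false(both$is_keystone[both$taxon_id == "a"])
})

test_that("indicator composites reproduce eigenstructure and variance shares", {
  # two perfectly correlated taxa -> PC1 explains everything
  x <- withr::with_seed(2, rpois(10, 40) + 1)
  ct <- make_counts(rbind(x, 2 * x, rep(1000, 10)))
  comp <- indicator_composite(ct, c("t1", "t2"))
  expect_equal(comp$var_explained[1], 1, tolerance = 1e-10)
  expect_error(indicator_composite(ct, "t1"), "2 indicator taxa")
  # component signs anchored: the largest-magnitude loading is positive
  ct2 <- withr::with_seed(8, make_counts(matrix(rpois(4 * 12, 50) + 1, 4, 12)))
  comp2 <- indicator_composite(ct2, rownames(ct2))
  for (j in seq_len(ncol(comp2$loadings)))
    expect_gt(comp2$loadings[which.max(abs(comp2$loadings[, j])), j], 0)
})
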