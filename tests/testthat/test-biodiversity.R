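test_that("richness counts non-zero taxa per sample", {
  ct <- cbind(s1 = c(0, 0, 0), s2 = c(5, 0, 1))
  rownames(ct) <- paste0("t", 1:3)
  expect_equal(unname(richness(ct)), c(0L, 2L))
  big <- withr::with_seed(1, matrix(rpois(100 * 6, 0.8), 100, 6,
                                    dimnames = list(paste0("t", 1:100), paste0("s", 1:6))))
  expect_equal(unname(richness(big)),
               unname(apply(big, 2, function(x) sum(x != 0))))
  expect_error(richness(cbind(c(-1, 2))), "non-negative")
})

test_that("Faith's PD matches hand-enumerated subtree sums", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  ct <- cbind(s1 = c(A = 1, B = 2, C = 0), s2 = c(A = 1, B = 1, C = 1))
  pd <- faith_pd(ct, tr)
  expect_equal(unname(pd["s1"]), 3)           # A,B plus the shared root edge
  expect_equal(unname(pd["s2"]), sum(tr$edge.length))
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  cts <- cbind(s = c(A = 1, B = 1, C = 1, D = 0))
  expect_equal(unname(faith_pd(cts, star)), 3)
  bad <- cbind(s = c(A = 1, Z = 1)); rownames(bad) <- c("A", "Z")
  expect_error(faith_pd(bad, tr), "Z")
})

test_that("Faith's PD agrees with picante::pd on rooted binary trees", {
  for (s in 1:5) {
    tr <- withr::with_seed(s, ape::rcoal(9, tip.label = paste0("t", 1:9)))
    ct <- withr::with_seed(40 + s,
                           matrix(rbinom(9 * 4, 1, 0.6), 9, 4,
                                  dimnames = list(tr$tip.label, paste0("s", 1:4))))
    ct[1, colSums(ct) == 0] <- 1
    ours <- faith_pd(ct, tr)
    ref <- picante::pd(t(ct), tr, include.root = TRUE)$PD
    expect_equal(unname(ours), ref, tolerance = 1e-10)
  }
})

test_that("Faith's PD agrees with the edge-enumeration oracle and is monotone", {
  for (s in 1:10) {
    tr <- withr::with_seed(s, ape::rcoal(12, tip.label = paste0("t", 1:12)))
    tips <- withr::with_seed(100 + s, sample(tr$tip.label, 5))
    ct <- matrix(0, 12, 2, dimnames = list(tr$tip.label, c("a", "b")))
    ct[tips, "a"] <- 1
    ct[c(tips, setdiff(tr$tip.label, tips)[1]), "b"] <- 1
    pd <- faith_pd(ct, tr)
    expect_equal(unname(pd["a"]), oracle_faith_pd(tr, tips), tolerance = 1e-10)
    expect_gte(pd[["b"]], pd[["a"]])   # adding a taxon never decreases PD
  }
})

test_that("Gower distance reproduces hand computations and its axioms", {
  tr <- data.frame(h = c(2, 4, 6), row.names = c("a", "b", "c"))
  D <- gower_distance(tr)
  expect_equal(D["a", "c"], 1)        # |2-6| / range 4
  expect_equal(D["a", "b"], 0.5)
  tr2 <- data.frame(h = c(2, 2), s = c(0, 10), row.names = c("a", "b"))
  expect_warning(D2 <- gower_distance(tr2), "zero-range")
  expect_equal(D2["a", "b"], 1)       # only the maximal trait remains
  tr3 <- data.frame(h = c(1, 1, 9), s = c(0, 10, 10), row.names = c("a", "b", "c"))
  expect_equal(gower_distance(tr3)["a", "b"], 0.5)  # mean of 0 and 1
  expect_identical(unname(diag(gower_distance(tr3))), rep(0, 3))
  expect_equal(gower_distance(tr3), t(gower_distance(tr3)))
  expect_true(all(gower_distance(tr3) >= 0 & gower_distance(tr3) <= 1))
})

test_that("Gower distance matches cluster::daisy on mixed numeric traits", {
  skip_if_not_installed("cluster")
  tr <- withr::with_seed(4, data.frame(h = runif(8, 1, 40), sla = rnorm(8, 15, 4),
                                       row.names = paste0("sp", 1:8)))
  D <- gower_distance(tr)
  Dd <- as.matrix(cluster::daisy(tr, metric = "gower"))
  expect_equal(unname(D), unname(Dd), tolerance = 1e-10)
})

test_that("FDis matches the geometry of small hand-solved cases", {
  # two species at embedded distance d, equal abundance -> d/2
  D <- matrix(c(0, 0.8, 0.8, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  ct <- cbind(s = c(a = 1, b = 1))
  expect_equal(unname(functional_dispersion(ct, D)), 0.4, tolerance = 1e-10)
  # three collinear points at 0, 1, 2 -> mean |x - 1| = 2/3
  pos <- c(a = 0, b = 1, c = 2)
  D3 <- abs(outer(pos, pos, `-`))
  ct3 <- cbind(s = c(a = 1, b = 1, c = 1))
  expect_equal(unname(functional_dispersion(ct3, D3)), 2 / 3, tolerance = 1e-8)
  # identical traits -> 0; single species -> 0
  D0 <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(unname(functional_dispersion(ct, D0)), 0)
  expect_equal(unname(functional_dispersion(cbind(s = c(a = 3, b = 0)), D)), 0)
})

test_that("FDis is label-invariant and scales with the distances", {
  tr <- withr::with_seed(6, data.frame(h = runif(6), s = runif(6),
                                       row.names = paste0("sp", 1:6)))
  D <- gower_distance(tr)
  ct <- withr::with_seed(7, matrix(rpois(6 * 4, 3), 6, 4,
                                   dimnames = list(rownames(tr), paste0("q", 1:4))))
  f1 <- functional_dispersion(ct, D)
  perm <- sample(rownames(tr))
  f2 <- functional_dispersion(ct[perm, ], D[perm, perm])
  expect_equal(f1, f2, tolerance = 1e-10)
  f3 <- functional_dispersion(ct, 2.5 * D)
  expect_equal(unname(f3), unname(2.5 * f1), tolerance = 1e-8)
})

test_that("beta distances follow the Bray-Curtis and Euclidean definitions", {
  ct <- cbind(s1 = c(1, 1), s2 = c(0, 2), s3 = c(1, 1))
  bc <- as.matrix(beta_distance(ct, "bray-curtis"))
  expect_equal(bc["s1", "s2"], 0.5)   # (|.5-0|+|.5-1|)/2 on relative abundances
  expect_equal(bc["s1", "s3"], 0)
  disj <- cbind(s1 = c(3, 0), s2 = c(0, 5))
  expect_equal(as.matrix(beta_distance(disj, "bray-curtis"))["s1", "s2"], 1)
  expect_error(beta_distance(cbind(s1 = c(0, 0), s2 = c(1, 1)), "bray-curtis"),
               "empty")
  fm <- rbind(p1 = c(0, 10), p2 = c(1, 20), p3 = c(2, 30))
  eu <- as.matrix(beta_distance(fm, "euclidean"))
  expect_equal(eu["p1", "p3"], 2 * eu["p1", "p2"], tolerance = 1e-10)
})

test_that("guild richness counts accepted-confidence guilds among present taxa", {
  ct <- cbind(s1 = c(t1 = 5, t2 = 1, t3 = 0), s2 = c(t1 = 0, t2 = 2, t3 = 3))
  gm <- data.frame(taxon_id = c("t1", "t2", "t3"),
                   guild = c("Saprotroph", "Saprotroph", "Endophyte"),
                   guild_confidence = c("Highly Probable", "Probable", "Possible"))
  gr <- guild_richness(ct, gm)
  expect_equal(unname(gr), c(1L, 1L))  # t3's low-confidence guild never counts
})
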