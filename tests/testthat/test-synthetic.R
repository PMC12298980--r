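test_that("function generator honours the no-effect and determinism limits", {
  des0 <- study_design(effect_profile = c(0, 0, 0), noise_sd = 1e-12, seed = 7)
  fx <- generate_functions(des0)
  gmeans <- apply(fx$functions, 2, tapply, fx$metadata$group, mean)
  expect_lt(max(apply(gmeans, 2, function(x) diff(range(x)))), 1e-8)

  des <- study_design(seed = 42)
  a <- generate_functions(des)
  b <- generate_functions(des)
  expect_identical(a$functions, b$functions)
  expect_identical(a$metadata, b$metadata)
})

test_that("planted group shifts are recovered at large n (law of large numbers)", {
  ep <- matrix(0, 3, 6, dimnames = list(NULL, c("PP", "SNP", "C", "N", "P", "redox")))
  ep[2, "PP"] <- 1   # +1 SD on PP functions in Y1
  des <- study_design(plots_per_group = 2000, effect_profile = ep, seed = 5)
  fx <- generate_functions(des)
  pp_cols <- names(fx$category)[fx$category == "PP"]
  g <- fx$metadata$group
  for (cc in pp_cols) {
    x <- fx$functions[, cc]
    pooled_sd <- sqrt(mean(tapply(x, g, var)))
    dstd <- (mean(x[g == "Y1"]) - mean(x[g == "Y0"])) / pooled_sd
    expect_lt(abs(dstd - 1), 0.05)
  }
})

test_that("metadata covariates follow the design (texture closure, SWC gradient)", {
  fx <- generate_functions(study_design(seed = 3))
  tex <- fx$metadata$clay + fx$metadata$silt + fx$metadata$sand
  expect_lt(max(abs(tex - 100)), 1e-9)
  swc_means <- tapply(fx$metadata$SWC, fx$metadata$group, mean)
  expect_true(swc_means["Y6"] > swc_means["Y0"])
})

test_that("community tables have the stated compositional structure", {
  des <- study_design(seed = 11)
  cm <- generate_community(des, "fungus")
  expect_true(all(colSums(cm$counts) == des$depth))
  expect_true(all(cm$counts >= 0), all(cm$counts == floor(cm$counts)))
  rel <- rowSums(cm$counts) / sum(cm$counts)
  expect_true(any(rel < 1e-4))   # at least one rare taxon
  expect_true(any(rel > 1e-3))   # at least one abundant taxon
  expect_true(all(cm$truth$indicators$taxon_id %in% rownames(cm$counts)))
  cm2 <- generate_community(des, "fungus")
  expect_identical(cm$counts, cm2$counts)
  expect_error(generate_community(study_design(enrichment = 1, seed = 1), "fungus"),
               "enrichment")
})

test_that("planted enrichment yields the intended relative-abundance ratio", {
  ratios <- c()
  for (s in 1:50) {
    des <- study_design(n_taxa_fun = 80, seed = 6000 + s)
    cm <- generate_community(des, "fungus")
    rel <- sweep(cm$counts, 2, colSums(cm$counts), `/`)
    grp <- rep(des$group_labels, each = des$plots_per_group)
    tr <- cm$truth$indicators
    for (k in seq_len(nrow(tr))) {
      ing <- grp == tr$group[k]
      ratios <- c(ratios, mean(rel[tr$taxon_id[k], ing]) /
                    mean(rel[tr$taxon_id[k], !ing]))
    }
  }
  expect_gt(mean(ratios), 6)
  expect_lt(mean(ratios), 10)
})

test_that("generated trees are bifurcating with every taxon as a tip", {
  ids <- paste0("t", 1:2)
  tr2 <- generate_tree(ids, seed = 1)
  expect_equal(tr2$Nnode, 1L)
  ids <- paste0("t", 1:17)
  tr <- generate_tree(ids, seed = 2)
  expect_equal(tr$Nnode, 16L)
  expect_setequal(tr$tip.label, ids)
  expect_true(all(tr$edge.length > 0))
  expect_identical(ape::write.tree(generate_tree(ids, seed = 9)),
                   ape::write.tree(generate_tree(ids, seed = 9)))
  expect_error(generate_tree(c("a", "a", "b")), "duplicate")
  expect_error(generate_tree("a"), "at least 2")
})

test_that("the linear SEM generator obeys the path-tracing rule", {
  null_dag <- dag_spec(data.frame(from = "X", to = "Y", beta = 0))
  d0 <- generate_sem_system(null_dag, 1000, seed = 3)
  expect_lt(abs(cor(d0$X, d0$Y)), 0.1)

  chain <- dag_spec(data.frame(from = c("X", "M"), to = c("M", "Y"),
                               beta = c(0.6, 0.6)))
  d <- generate_sem_system(chain, 10000, seed = 4)
  expect_lt(abs(cor(d$X, d$Y) - 0.36), 0.03)
  expect_lt(max(abs(apply(d, 2, var) - 1)), 0.1)
  expect_identical(generate_sem_system(chain, 50, seed = 8),
                   generate_sem_system(chain, 50, seed = 8))
  expect_error(dag_spec(data.frame(from = c("A", "B"), to = c("B", "A"))),
               "cycle")
})

test_that("a study round-trips through write_study/read_study", {
  des <- study_design(n_taxa_pro = 40, n_taxa_fun = 30, n_indicator_planted = 6,
                      depth = 2000, seed = 13)
  st <- generate_study(des)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  rt <- read_study(dir)
  expect_equal(rt$functions, st$functions, tolerance = 1e-12)
  expect_identical(rt$communities$fungus$counts, st$communities$fungus$counts)
  expect_setequal(rt$trees$plant$tip.label, st$trees$plant$tip.label)
  expect_equal(rt$truth$indicators$fungus$taxon_id,
               st$truth$indicators$fungus$taxon_id)
  expect_equal(rt$truth$sem$beta, st$truth$sem$beta, tolerance = 1e-12)
  expect_equal(rt$truth$modules$fungus, st$truth$modules$fungus)
})
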