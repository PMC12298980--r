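#' Describe a synthetic study design
#'
#' Captures the layout of the field campaign the generator emulates: a
#' chronosequence of disturbance ages (groups `Y0` = undisturbed, `Y1` = one
#' year after installation, `Y6` = six years after), six plots per group,
#' 23 ecosystem functions in six categories (primary production PP, soil
#' nutrient pool SNP, carbon/nitrogen/phosphorus cycling, redox), plus
#' prokaryotic, fungal and plant communities.
#'
#' @param n_groups Number of chronosequence groups (default 3).
#' @param plots_per_group Plots per group (default 6; must be >= 3).
#' @param n_functions Number of ecosystem functions (default 23).
#' @param categories Named integer vector mapping category to the number of
#'   functions it contains; must sum to `n_functions`.
#' @param n_taxa_pro,n_taxa_fun,n_taxa_plant Taxon pool sizes per domain.
#' @param n_indicator_planted Number of planted group-associated indicator
#'   taxa per microbial domain.
#' @param effect_profile Per-group mean shift on the function z-scale. A
#'   numeric vector of length `n_groups` (same shift for every function), or
#'   a `n_groups x length(categories)` matrix for per-category shifts. The
#'   default encodes a strong installation pulse and a weak running drift
#'   (`Y0 = 0`, `Y1 = 1.2`, `Y6 = 1.5`).
#' @param noise_sd Scale of the stochastic part of each function (z-scale).
#' @param rho_cat Within-category correlation imposed via a shared latent
#'   factor (default 0.5).
#' @param depth Sequencing depth per microbial sample (reads).
#' @param plant_depth Expected total individuals per plant quadrat.
#' @param enrichment Multiplicative enrichment of planted indicators in
#'   their associated group (default 8).
#' @param module_loading Loading of the latent module factor that induces
#'   co-occurrence (default 0.7).
#' @param n_modules Number of latent co-occurrence modules per domain.
#' @param seed Master seed; every stochastic stage derives its own stream.
#' @return A `study_design` list, validated.
#' @export
study_design <- function(n_groups = 3,
                         plots_per_group = 6,
                         n_functions = 23,
                         categories = c(PP = 2, SNP = 5, C = 6, N = 5, P = 3, redox = 2),
                         n_taxa_pro = 200,
                         n_taxa_fun = 120,
                         n_taxa_plant = 12,
                         n_indicator_planted = 25,
                         effect_profile = c(Y0 = 0, Y1 = 1.2, Y6 = 1.5),
                         noise_sd = 1,
                         rho_cat = 0.5,
                         depth = 50000,
                         plant_depth = 150,
                         enrichment = 8,
                         module_loading = 0.7,
                         n_modules = 6,
                         seed = 1) {
  for (nm in c("n_groups", "plots_per_group", "n_functions", "n_taxa_pro",
               "n_taxa_fun", "n_taxa_plant", "depth", "plant_depth", "n_modules"))
    stop_if_not_count(get(nm), nm)
  if (plots_per_group < 3) stop("plots_per_group must be >= 3")
  if (!is.numeric(categories) || is.null(names(categories)))
    stop("categories must be a named integer vector")
  if (sum(categories) != n_functions)
    stop("category sizes must sum to n_functions")
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop("noise_sd must be positive")
  if (rho_cat < 0 || rho_cat >= 1) stop("rho_cat must be in [0, 1)")
  if (n_indicator_planted < 0) stop("n_indicator_planted must be >= 0")
  grp <- if (n_groups == 3) c("Y0", "Y1", "Y6") else paste0("G", seq_len(n_groups))
  if (is.matrix(effect_profile)) {
    if (nrow(effect_profile) != n_groups || ncol(effect_profile) != length(categories))
      stop("matrix effect_profile must be n_groups x n_categories")
  } else if (length(effect_profile) != n_groups) {
    stop("effect_profile must have one entry per group")
  }
  structure(list(
    n_groups = n_groups, group_labels = grp, plots_per_group = plots_per_group,
    n_functions = n_functions, categories = categories,
    n_taxa_pro = n_taxa_pro, n_taxa_fun = n_taxa_fun, n_taxa_plant = n_taxa_plant,
    n_indicator_planted = n_indicator_planted, effect_profile = effect_profile,
    noise_sd = noise_sd, rho_cat = rho_cat, depth = depth,
    plant_depth = plant_depth, enrichment = enrichment,
    module_loading = module_loading, n_modules = n_modules,
    seed = as.integer(seed)
  ), class = "study_design")
}

## expand effect_profile to an n_groups x n_functions shift matrix
expand_effect_profile <- function(design) {
  cat_of <- rep(names(design$categories), design$categories)
  if (is.matrix(design$effect_profile)) {
    ep <- design$effect_profile
    colnames(ep) <- names(design$categories)
    ep[, cat_of, drop = FALSE]
  } else {
    matrix(design$effect_profile, nrow = design$n_groups,
           ncol = design$n_functions)
  }
}

#' Generate the plot-by-function table and plot metadata
#'
#' Each function value is `mu_f + scale_f * (shift_g + noise_sd *
#' (sqrt(rho) * F_cat + sqrt(1 - rho) * eps))` where `F_cat` is a latent
#' per-plot factor shared by all functions of the same category (imposing
#' within-category correlation `rho`), `shift_g` is the group mean shift on
#' the z-scale and `mu_f`, `scale_f` set arbitrary native units. Metadata
#' covariates follow the disturbance gradient: soil water content (SWC)
#' increases with group index while soil temperature and evaporation
#' decrease; texture fractions are generated on the simplex and sum to 100.
#'
#' @param design A [study_design()].
#' @return List with `functions` (plots x functions matrix), `metadata`
#'   (data.frame: plot_id, group, SWC, ST, pH, evaporation, clay, silt,
#'   sand), and `category` (named map function id -> category).
#' @export
generate_functions <- function(design) {
  stopifnot(inherits(design, "study_design"))
  local_seed(sub_seed(design$seed, "functions"), {
    G <- design$n_groups; P <- design$plots_per_group
    n_plot <- G * P; n_fun <- design$n_functions
    cat_of <- rep(names(design$categories), design$categories)
    fun_ids <- sprintf("F%02d_%s", seq_len(n_fun), cat_of)
    plot_ids <- paste0(rep(design$group_labels, each = P), "_p", rep(seq_len(P), G))
    group <- rep(design$group_labels, each = P)
    gidx <- rep(seq_len(G), each = P)

    shift <- expand_effect_profile(design)            # G x n_fun
    rho <- design$rho_cat
    lat <- matrix(rnorm(n_plot * length(design$categories)), n_plot)
    colnames(lat) <- names(design$categories)
    eps <- matrix(rnorm(n_plot * n_fun), n_plot, n_fun)
    z <- shift[gidx, , drop = FALSE] +
      design$noise_sd * (sqrt(rho) * lat[, cat_of, drop = FALSE] +
                           sqrt(1 - rho) * eps)
    mu_f <- runif(n_fun, 5, 80)
    scale_f <- runif(n_fun, 0.5, 5)
    fm <- sweep(sweep(z, 2, scale_f, `*`), 2, mu_f, `+`)
    dimnames(fm) <- list(plot_ids, fun_ids)

    tex <- t(apply(matrix(rgamma(n_plot * 3, shape = c(12, 30, 58)), 3), 2,
                   function(x) 100 * x / sum(x)))
    metadata <- data.frame(
      plot_id = plot_ids, group = group,
      SWC = 8 + 2.5 * (gidx - 1) + rnorm(n_plot, 0, 1),
      ST = 18 - 1.5 * (gidx - 1) + rnorm(n_plot, 0, 0.8),
      pH = 8.2 + rnorm(n_plot, 0, 0.15),
      evaporation = 1700 - 80 * (gidx - 1) + rnorm(n_plot, 0, 40),
      clay = tex[, 1], silt = tex[, 2], sand = tex[, 3],
      stringsAsFactors = FALSE
    )
    list(functions = fm, metadata = metadata,
         category = setNames(cat_of, fun_ids))
  })
}

phyla_pool <- list(
  prokaryote = c("Actinobacteriota", "Proteobacteria", "Acidobacteriota",
                 "Chloroflexi", "Bacteroidota", "Gemmatimonadota"),
  fungus = c("Ascomycota", "Basidiomycota", "Mortierellomycota",
             "Glomeromycota", "Chytridiomycota"),
  plant = c("Poaceae", "Asteraceae", "Fabaceae", "Chenopodiaceae")
)
guild_pool <- c("Arbuscular Mycorrhizal", "Plant Pathogen", "Saprotroph",
                "Endophyte", "Ectomycorrhizal", "Animal Pathogen",
                "Lichenized", "Wood Saprotroph")

#' Generate a compositional community table with planted structure
#'
#' Taxon base abundances are log-normal (sigma = 2), giving the heavy
#' rare/abundant tail the screening thresholds rely on. Taxa are assigned to
#' latent modules; a per-sample module factor (loading `module_loading`)
#' induces co-occurrence. Planted indicator taxa receive a multiplicative
#' enrichment in their associated group. Counts are multinomial draws at the
#' configured depth, so column sums equal the depth exactly. One taxon is
#' guaranteed below 0.01% and one above 0.1% overall relative abundance.
#'
#' @param design A [study_design()].
#' @param domain One of `"prokaryote"`, `"fungus"`, `"plant"`.
#' @param force_null_enrichment If `TRUE`, permits enrichment factor 1 to
#'   build a null community with nominally "planted" but unenriched taxa.
#' @return List with `counts` (taxa x samples integer matrix), `taxonomy`
#'   (data.frame with taxonomy strings and, for microbes, a functional
#'   guild/pathway label with a confidence rank), and `truth` (planted
#'   indicator taxa with their group, and module membership).
#' @export
generate_community <- function(design, domain = c("prokaryote", "fungus", "plant"),
                               force_null_enrichment = FALSE) {
  stopifnot(inherits(design, "study_design"))
  domain <- match.arg(domain)
  enr <- design$enrichment
  if (enr <= 1 && !force_null_enrichment)
    stop("enrichment factor must be > 1 for planted indicators")
  if (enr < 1) stop("enrichment factor must be >= 1")
  n_taxa <- switch(domain, prokaryote = design$n_taxa_pro,
                   fungus = design$n_taxa_fun, plant = design$n_taxa_plant)
  depth <- if (domain == "plant") design$plant_depth else design$depth
  n_ind <- if (domain == "plant") 0L else min(design$n_indicator_planted, n_taxa)

  local_seed(sub_seed(design$seed, paste0("community_", domain)), {
    G <- design$n_groups; P <- design$plots_per_group
    n_samp <- G * P
    sample_ids <- paste0(rep(design$group_labels, each = P), "_p",
                         rep(seq_len(P), G))
    gidx <- rep(seq_len(G), each = P)
    prefix <- switch(domain, prokaryote = "Pro", fungus = "Fun", plant = "Plant")
    taxa_ids <- sprintf("%s_ASV%04d", prefix, seq_len(n_taxa))
    if (domain == "plant") taxa_ids <- sprintf("Plant_sp%02d", seq_len(n_taxa))

    base <- rnorm(n_taxa, 0, 2)
    ## guarantee the rare/abundant tail regardless of draw
    tot <- sum(exp(base))
    base[which.min(base)] <- log(tot * 5e-5)
    base[which.max(base)] <- max(base[which.max(base)], log(tot * 5e-3))

    modules <- setNames(rep_len(seq_len(design$n_modules), n_taxa), taxa_ids)
    lam <- design$module_loading
    u <- matrix(rnorm(design$n_modules * n_samp), design$n_modules, n_samp)
    e <- matrix(rnorm(n_taxa * n_samp), n_taxa, n_samp)
    logint <- base + lam * u[modules, , drop = FALSE] + sqrt(1 - lam^2) * e

    ind_truth <- data.frame(taxon_id = character(0), group = character(0))
    if (n_ind > 0) {
      ## plant indicators among mid-abundance taxa: abundant enough to be
      ## observed at the configured depth, but carrying so little total mass
      ## that their enrichment leaves the other taxa's relative abundances
      ## essentially unchanged (keeps the enriched/other ratio near the
      ## nominal enrichment factor and the non-planted taxa truly null)
      erel <- exp(base) / sum(exp(base))
      eligible <- which(erel >= 2e-4 & erel <= 2e-3)
      if (length(eligible) < n_ind)
        eligible <- setdiff(order(abs(log(erel / 6e-4))), which.min(base))[
          seq_len(min(n_taxa - 1L, max(n_ind, length(eligible))))]
      ind_idx <- sample(eligible, n_ind)
      ind_grp <- rep_len(seq_len(G), n_ind)
      for (k in seq_len(n_ind))
        logint[ind_idx[k], gidx == ind_grp[k]] <-
          logint[ind_idx[k], gidx == ind_grp[k]] + log(enr)
      ind_truth <- data.frame(taxon_id = taxa_ids[ind_idx],
                              group = design$group_labels[ind_grp],
                              stringsAsFactors = FALSE)
    }

    counts <- vapply(seq_len(n_samp), function(s) {
      p <- exp(logint[, s]); p <- p / sum(p)
      rmultinom(1, depth, p)[, 1]
    }, integer(n_taxa))
    dimnames(counts) <- list(taxa_ids, sample_ids)

    phy <- sample(phyla_pool[[domain]], n_taxa, replace = TRUE)
    taxonomy <- data.frame(
      taxon_id = taxa_ids,
      taxonomy = sprintf("d__%s;p__%s;g__g%03d",
                         switch(domain, prokaryote = "Bacteria",
                                fungus = "Fungi", plant = "Viridiplantae"),
                         phy, seq_len(n_taxa)),
      stringsAsFactors = FALSE
    )
    if (domain != "plant") {
      taxonomy$guild <- sample(guild_pool, n_taxa, replace = TRUE)
      taxonomy$guild_confidence <- sample(
        c("Highly Probable", "Probable", "Possible"), n_taxa,
        replace = TRUE, prob = c(0.35, 0.4, 0.25))
    }
    list(counts = counts, taxonomy = taxonomy,
         truth = list(indicators = ind_truth, modules = modules))
  })
}

#' Generate a random bifurcating tree over a set of taxa
#'
#' Uniform coalescent-style joins via [ape::rcoal()]; branch lengths are
#' strictly positive and every taxon appears exactly once as a tip.
#'
#' @param taxa_ids Character vector of unique tip labels (length >= 2).
#' @param seed Integer seed.
#' @return An [ape::phylo] object.
#' @export
generate_tree <- function(taxa_ids, seed = 1) {
  if (length(taxa_ids) < 2) stop("need at least 2 taxa to build a tree")
  if (anyDuplicated(taxa_ids)) stop("duplicate taxon IDs are not allowed")
  local_seed(sub_seed(seed, "tree"), {
    tr <- ape::rcoal(length(taxa_ids), tip.label = as.character(taxa_ids))
    tr$edge.length <- pmax(tr$edge.length, 1e-8)
    tr
  })
}

#' Simulate data from a linear Gaussian structural equation system
#'
#' Variables are generated in topological order as linear combinations of
#' their parents plus Gaussian noise. Noise variances are solved from the
#' implied covariance recursion so that every variable has population
#' variance exactly 1; coefficients are therefore standardized path
#' coefficients and the path-tracing rule applies.
#'
#' @param dag A [dag_spec()] whose edge list carries a `beta` column, or a
#'   data.frame with columns `from`, `to`, `beta`.
#' @param n Number of observations.
#' @param seed Integer seed.
#' @return `data.frame` of `n` rows, one column per node.
#' @export
generate_sem_system <- function(dag, n, seed = 1) {
  if (is.data.frame(dag)) dag <- dag_spec(dag)
  stopifnot(inherits(dag, "dag_spec"))
  if (is.null(dag$edges$beta))
    stop("dag edge list must carry a 'beta' column of true coefficients")
  nodes <- dag$topo_order
  k <- length(nodes)
  ## implied covariance, built in topological order with unit variances
  S <- diag(1, k); dimnames(S) <- list(nodes, nodes)
  psi <- setNames(rep(1, k), nodes)
  B <- matrix(0, k, k, dimnames = list(nodes, nodes))   # B[parent, child]
  for (i in seq_len(nrow(dag$edges)))
    B[dag$edges$from[i], dag$edges$to[i]] <- dag$edges$beta[i]
  for (v in nodes) {
    pa <- nodes[B[, v] != 0]
    if (!length(pa)) next
    b <- B[pa, v]
    for (u in nodes) if (u != v)
      S[u, v] <- S[v, u] <- sum(b * S[pa, u])
    ev <- 1 - drop(t(b) %*% S[pa, pa, drop = FALSE] %*% b)
    if (ev <= 0)
      stop(sprintf("coefficients into '%s' imply variance > 1; reduce betas", v))
    psi[v] <- ev
    S[v, v] <- 1
  }
  local_seed(sub_seed(seed, "sem_system"), {
    X <- matrix(0, n, k, dimnames = list(NULL, nodes))
    for (v in nodes) {
      pa <- nodes[B[, v] != 0]
      mu <- if (length(pa)) X[, pa, drop = FALSE] %*% B[pa, v] else 0
      X[, v] <- mu + rnorm(n, 0, sqrt(psi[v]))
    }
    as.data.frame(X)
  })
}

#' Generate a complete synthetic study
#'
#' Bundles every input the pipeline consumes: function matrix + metadata,
#' three community tables with planted indicators and modules, phylogenies,
#' plant traits, raw microbial activity measurements coupled to the
#' disturbance gradient (biomass and gene copies rise, the metabolic
#' quotient falls), a plot-level driver table drawn from the default true
#' path model, and a truth record sufficient to score recovery.
#'
#' @param design A [study_design()].
#' @return A `synthetic_study` list.
#' @export
generate_study <- function(design = study_design()) {
  stopifnot(inherits(design, "study_design"))
  fx <- generate_functions(design)
  comm <- list(
    prokaryote = generate_community(design, "prokaryote"),
    fungus = generate_community(design, "fungus"),
    plant = generate_community(design, "plant")
  )
  trees <- list(
    prokaryote = generate_tree(rownames(comm$prokaryote$counts),
                               sub_seed(design$seed, "tr_pro")),
    fungus = generate_tree(rownames(comm$fungus$counts),
                           sub_seed(design$seed, "tr_fun")),
    plant = generate_tree(rownames(comm$plant$counts),
                          sub_seed(design$seed, "tr_plant"))
  )
  n_plot <- design$n_groups * design$plots_per_group
  gidx <- rep(seq_len(design$n_groups), each = design$plots_per_group)
  traits <- local_seed(sub_seed(design$seed, "traits"), data.frame(
    species = rownames(comm$plant$counts),
    height = exp(rnorm(design$n_taxa_plant, log(20), 0.5)),
    SLA = pmax(rnorm(design$n_taxa_plant, 15, 4), 2),
    stringsAsFactors = FALSE
  ))
  activity_raw <- local_seed(sub_seed(design$seed, "activity"), data.frame(
    plot_id = fx$metadata$plot_id,
    copies_pro = 10^(9 + 0.25 * (gidx - 1) + rnorm(n_plot, 0, 0.15)),
    copies_fun = 10^(7.5 + 0.3 * (gidx - 1) + rnorm(n_plot, 0, 0.15)),
    mbc = 250 * (1 + 0.35 * (gidx - 1)) * exp(rnorm(n_plot, 0, 0.1)),
    soc = 9 * (1 + 0.12 * (gidx - 1)) * exp(rnorm(n_plot, 0, 0.08)),
    c_min = 2.2 * (1 + 0.15 * (gidx - 1)) * exp(rnorm(n_plot, 0, 0.1)),
    stringsAsFactors = FALSE
  ))
  dag <- default_dag()
  drivers <- generate_sem_system(dag, n_plot, sub_seed(design$seed, "drivers"))
  drivers <- cbind(plot_id = fx$metadata$plot_id, drivers)
  truth <- list(
    indicators = list(prokaryote = comm$prokaryote$truth$indicators,
                      fungus = comm$fungus$truth$indicators),
    modules = list(prokaryote = comm$prokaryote$truth$modules,
                   fungus = comm$fungus$truth$modules),
    sem = dag$edges,
    group_effects = expand_effect_profile(design),
    seed = design$seed
  )
  structure(list(design = design, functions = fx$functions,
                 category = fx$category, metadata = fx$metadata,
                 communities = comm, trees = trees, traits = traits,
                 activity_raw = activity_raw, drivers = drivers,
                 truth = truth),
            class = "synthetic_study")
}

#' Write a synthetic study to a directory of plain-text files
#'
#' Emits `functions.tsv`, `metadata.tsv`, `community_<domain>.tsv` (taxa x
#' samples), `taxonomy_<domain>.tsv`, `tree_<domain>.nwk`,
#' `traits_plant.tsv`, `activity.tsv`, `drivers.tsv` and `truth.json`.
#' All tables are UTF-8, tab-delimited, with `.` as decimal separator.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f, rn = FALSE) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE,
    row.names = rn, col.names = TRUE, fileEncoding = "UTF-8")
  fm <- data.frame(plot_id = rownames(study$functions), study$functions,
                   check.names = FALSE)
  wt(fm, "functions.tsv")
  wt(data.frame(function_id = names(study$category),
                category = unname(study$category)), "function_categories.tsv")
  wt(study$metadata, "metadata.tsv")
  for (d in names(study$communities)) {
    cm <- study$communities[[d]]
    wt(data.frame(taxon_id = rownames(cm$counts), cm$counts,
                  check.names = FALSE), paste0("community_", d, ".tsv"))
    wt(cm$taxonomy, paste0("taxonomy_", d, ".tsv"))
    ape::write.tree(study$trees[[d]], file.path(dir, paste0("tree_", d, ".nwk")))
  }
  wt(study$traits, "traits_plant.tsv")
  wt(study$activity_raw, "activity.tsv")
  wt(study$drivers, "drivers.tsv")
  truth <- study$truth
  truth$modules <- lapply(truth$modules, as.list)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#' @param dir Directory path.
#' @return A `synthetic_study`-like list (without the design object).
#' @export
read_study <- function(dir) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing input file: ", f, call. = FALSE)
    p
  }
  rt <- function(f) utils::read.table(need(f), sep = "\t",
                                      header = TRUE, check.names = FALSE,
                                      stringsAsFactors = FALSE)
  fm <- rt("functions.tsv")
  functions <- as.matrix(fm[, -1, drop = FALSE])
  rownames(functions) <- fm$plot_id
  cats <- rt("function_categories.tsv")
  domains <- c("prokaryote", "fungus", "plant")
  communities <- lapply(domains, function(d) {
    cm <- rt(paste0("community_", d, ".tsv"))
    counts <- as.matrix(cm[, -1, drop = FALSE])
    rownames(counts) <- cm$taxon_id
    storage.mode(counts) <- "integer"
    list(counts = counts, taxonomy = rt(paste0("taxonomy_", d, ".tsv")))
  })
  names(communities) <- domains
  trees <- lapply(domains, function(d)
    ape::read.tree(need(paste0("tree_", d, ".nwk"))))
  names(trees) <- domains
  truth <- NULL
  if (file.exists(file.path(dir, "truth.json"))) {
    truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                                 simplifyVector = TRUE)
    truth$modules <- lapply(truth$modules, function(m)
      setNames(as.integer(unlist(m)), names(m)))
  }
  structure(list(
    functions = functions,
    category = setNames(cats$category, cats$function_id),
    metadata = rt("metadata.tsv"),
    communities = communities, trees = trees,
    traits = rt("traits_plant.tsv"),
    activity_raw = rt("activity.tsv"),
    drivers = rt("drivers.tsv"),
    truth = truth
  ), class = "synthetic_study")
}
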