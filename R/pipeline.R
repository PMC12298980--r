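#' Assemble the plot-level driver table for attribution and SEM
#'
#' Builds the composite driver variables from stage outputs: `MA` (activity
#' composite PC1), `Div` (PC1 of the alpha-diversity indices across
#' domains), `ind_fun` / `ind_pro` (PC1 of the indicator-taxon composites)
#' and `Env` (PC1 of the environmental covariates), plus the EMF responses
#' and the function-category composites (PP, SNP, Cycling from the
#' standardized function means).
#'
#' @param study A `synthetic_study` (or [read_study()] result).
#' @param screen_fun,screen_pro [indval()] tables for fungi / prokaryotes.
#' @param emf [emf_profile()] table.
#' @param diversity Named list of [diversity_profile()] tables per domain.
#' @param activity [compute_activity_indices()] table.
#' @return data.frame, one row per plot.
#' @export
build_driver_table <- function(study, screen_fun, screen_pro, emf,
                               diversity, activity) {
  md <- study$metadata
  env_mat <- as.matrix(md[c("SWC", "ST", "pH", "evaporation", "clay", "silt", "sand")])
  rownames(env_mat) <- md$plot_id
  env <- pca_anchored(env_mat, anchor = "SWC")$scores[, 1]

  div_cols <- lapply(names(diversity), function(d) {
    dv <- diversity[[d]]
    num <- dv[setdiff(names(dv), "sample_id")]
    names(num) <- paste0(d, "_", names(num))
    num
  })
  div_mat <- as.matrix(do.call(cbind, div_cols))
  rownames(div_mat) <- diversity[[1]]$sample_id
  div <- pca_anchored(div_mat)$scores[, 1]

  ma <- activity_composite(activity)$scores

  comp_ind <- function(ct, screen) {
    taxa <- screen$taxon_id[screen$is_indicator]
    if (length(taxa) < 2) taxa <- screen$taxon_id[order(screen$p_perm)][1:2]
    indicator_composite(ct, taxa)$scores[, 1]
  }
  ind_fun <- comp_ind(study$communities$fungus$counts, screen_fun)
  ind_pro <- comp_ind(study$communities$prokaryote$counts, screen_pro)

  cyc <- rowMeans(as.matrix(emf[paste0("cat_", c("C", "N", "P"))]))
  data.frame(
    plot_id = md$plot_id, group = md$group,
    Env = unname(env[md$plot_id]),
    MA = unname(ma[md$plot_id]),
    Div = unname(div[md$plot_id]),
    ind_fun = unname(ind_fun[md$plot_id]),
    ind_pro = unname(ind_pro[md$plot_id]),
    Indicator = unname((scale(ind_fun[md$plot_id])[, 1] +
                          scale(ind_pro[md$plot_id])[, 1]) / 2),
    PP = emf$cat_PP, SNP = emf$cat_SNP, Cycling = unname(cyc),
    EMF = emf$avgFunc,
    stringsAsFactors = FALSE
  )
}

#' OLS scan of diversity metrics against EMF
#'
#' Single-predictor linear fits of each diversity index on avgFunc, the
#' degenerate one-variable case of the importance battery.
#'
#' @param diversity Named list of [diversity_profile()] tables.
#' @param emf [emf_profile()] table (matched by sample/plot id).
#' @return data.frame: domain, metric, slope, r2, p.
#' @export
diversity_emf_scan <- function(diversity, emf) {
  rows <- list()
  for (d in names(diversity)) {
    dv <- diversity[[d]]
    y <- emf$avgFunc[match(dv$sample_id, emf$plot_id)]
    for (m in setdiff(names(dv), "sample_id")) {
      x <- dv[[m]]
      if (sd(x) == 0) next
      fit <- summary(lm(y ~ x))
      rows[[length(rows) + 1]] <- data.frame(
        domain = d, metric = m, slope = fit$coefficients[2, 1],
        r2 = fit$r.squared, p = fit$coefficients[2, 4],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the full analysis pipeline on a study
#'
#' Orchestrates simulate (optional) -> EMF indices and effect sizes ->
#' diversity -> taxa screens -> activity -> attribution -> piecewise SEM,
#' writing each stage's tables under `out_dir/<stage>/` plus a
#' `manifest.json` with the configuration, seeds and versions. Re-running
#' with the same config reproduces every output.
#'
#' @param config Named list (or path to a YAML file) with elements:
#'   `out_dir` (required); either `simulate` (a list of [study_design()]
#'   arguments) or `input_dir` (a directory readable by [read_study()]);
#'   optional `seed` (default 1), `n_perm` (default 999), `n_boot`
#'   (default 2000), `thresholds` (default `c(20, 40, 60, 80)`), `dag`
#'   (character edge lines, default [default_dag()]).
#' @return Invisibly, a list of all stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  known <- c("out_dir", "simulate", "input_dir", "seed", "n_perm", "n_boot",
             "thresholds", "dag")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  seed <- config$seed %||% 1
  n_perm <- config$n_perm %||% 999
  n_boot <- config$n_boot %||% 2000
  thresholds <- config$thresholds %||% c(20, 40, 60, 80)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_line <- function(...) message(format(Sys.time(), "%H:%M:%S"),
                                    " [pipeline] ", ...)
  stage_dir <- function(s) {
    d <- file.path(out_dir, s); dir.create(d, showWarnings = FALSE); d
  }
  wt <- function(x, dir, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  run_stage <- function(name, fn) {
    log_line("stage ", name)
    tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  study <- run_stage("simulate", function() {
    if (!is.null(config$input_dir)) {
      for (f in c("functions.tsv", "metadata.tsv"))
        if (!file.exists(file.path(config$input_dir, f)))
          stop("missing input file: ", f)
      read_study(config$input_dir)
    } else {
      des <- do.call(study_design, c(config$simulate %||% list(),
                                     if (is.null(config$simulate$seed))
                                       list(seed = seed)))
      st <- generate_study(des)
      write_study(st, stage_dir("simulate"))
      st
    }
  })

  emf_res <- run_stage("emf", function() {
    d <- stage_dir("emf")
    prof <- emf_profile(study$functions, study$category,
                        thresholds = thresholds)
    groups <- study$metadata$group
    idx <- list(installation = c("Y1", "Y0", 1, 0),
                running = c("Y6", "Y1", 6, 1))
    effs <- list()
    for (ind in setdiff(names(prof), "plot_id")) {
      for (per in names(idx)) {
        gi <- idx[[per]]
        e <- annual_effect_size(prof[[ind]][groups == gi[1]],
                                prof[[ind]][groups == gi[2]],
                                i = as.numeric(gi[3]), j = as.numeric(gi[4]),
                                n_boot = n_boot, seed = seed)
        effs[[length(effs) + 1]] <- data.frame(
          indicator = ind, period = per, effect = e$effect,
          ci_low = e$ci_low, ci_high = e$ci_high)
      }
    }
    effects <- do.call(rbind, effs)
    kw <- do.call(rbind, lapply(setdiff(names(prof), "plot_id"), function(ind) {
      k <- compare_groups(prof[[ind]], groups)
      data.frame(indicator = ind, H = k$H, p = k$p)
    }))
    wt(prof, d, "emf_profile.tsv"); wt(effects, d, "effect_sizes.tsv")
    wt(kw, d, "kruskal_wallis.tsv")
    list(profile = prof, effects = effects, kruskal = kw)
  })

  div_res <- run_stage("diversity", function() {
    d <- stage_dir("diversity")
    out <- list()
    for (dom in names(study$communities)) {
      cm <- study$communities[[dom]]
      tree <- study$trees[[dom]]
      if (is.null(tree)) stop("missing tree for domain ", dom)
      guild <- if (!is.null(cm$taxonomy$guild)) cm$taxonomy else NULL
      traits <- if (dom == "plant") study$traits else NULL
      out[[dom]] <- diversity_profile(cm$counts, tree = tree,
                                      traits = traits, guild_map = guild)
      wt(out[[dom]], d, paste0("diversity_", dom, ".tsv"))
    }
    out
  })

  screen_res <- run_stage("screen", function() {
    d <- stage_dir("screen")
    out <- list()
    for (dom in c("prokaryote", "fungus")) {
      ct <- filter_asvs(study$communities[[dom]]$counts)
      iv <- indval(ct, study$metadata$group, n_perm = n_perm, seed = seed)
      ab <- classify_abundance(study$communities[[dom]]$counts)
      net <- suppressWarnings(build_network(ct))
      mods <- detect_modules(net)
      topo <- zi_pi(net, mods)
      wt(iv, d, paste0("indicators_", dom, ".tsv"))
      wt(ab, d, paste0("abundance_classes_", dom, ".tsv"))
      wt(topo, d, paste0("node_topology_", dom, ".tsv"))
      out[[dom]] <- list(filtered = ct, indval = iv, abundance = ab,
                         network = net, modules = mods, topology = topo)
    }
    out
  })

  act_res <- run_stage("activity", function() {
    d <- stage_dir("activity")
    idx <- compute_activity_indices(study$activity_raw)
    wt(idx, d, "activity_indices.tsv")
    idx
  })

  attr_res <- run_stage("attribute", function() {
    d <- stage_dir("attribute")
    drv <- build_driver_table(study, screen_res$fungus$indval,
                              screen_res$prokaryote$indval,
                              emf_res$profile, div_res, act_res)
    wt(drv, d, "drivers.tsv")
    groups <- list(MA = "MA", Div = "Div",
                   Indicator = c("ind_fun", "ind_pro"), Env = "Env")
    vp <- variance_partition(drv$EMF, drv, groups)
    lmg <- lmg_importance(drv$EMF, drv[c("MA", "Div", "ind_fun", "ind_pro", "Env")])
    pc <- do.call(rbind, lapply(c("MA", "Div", "Indicator", "Env"), function(v) {
      ctrl <- setdiff(c("MA", "Div", "Indicator", "Env"), v)
      r <- partial_correlation(drv$EMF, drv[[v]], drv[ctrl])
      data.frame(variable = v, r = r$r, p = r$p)
    }))
    rf <- rf_importance(drv$EMF,
                        drv[c("MA", "Div", "ind_fun", "ind_pro", "Env")],
                        n_perm = min(n_perm, 99), seed = seed)
    mt <- {
      bc <- beta_distance(screen_res$fungus$filtered, "bray-curtis")
      fd <- beta_distance(study$functions, "euclidean")
      m <- mantel_test(bc, fd, n_perm = n_perm, seed = seed)
      data.frame(pair = "fungal_community_vs_functions", r = m$r, p = m$p)
    }
    scan <- diversity_emf_scan(div_res, emf_res$profile)
    wt(data.frame(component = names(vp$components),
                  fraction = unname(vp$components)), d, "vpa.tsv")
    wt(data.frame(variable = names(lmg), share = unname(lmg)), d, "lmg.tsv")
    wt(pc, d, "partial_correlation.tsv")
    wt(rf, d, "rf_importance.tsv")
    wt(mt, d, "mantel.tsv")
    wt(scan, d, "diversity_emf_scan.tsv")
    list(drivers = drv, vpa = vp, lmg = lmg, pcor = pc, rf = rf,
         mantel = mt, scan = scan)
  })

  sem_res <- run_stage("sem", function() {
    d <- stage_dir("sem")
    dag <- if (!is.null(config$dag)) dag_spec(config$dag) else default_dag()
    drv <- attr_res$drivers
    inst <- drv[drv$group %in% c("Y0", "Y1"), ]
    runn <- drv[drv$group %in% c("Y1", "Y6"), ]
    cp <- compare_periods(dag, inst, runn)
    wt(cp$installation$coefficients, d, "edges_installation.tsv")
    wt(cp$running$coefficients, d, "edges_running.tsv")
    wt(cp$installation$claims, d, "claims_installation.tsv")
    wt(cp$running$claims, d, "claims_running.tsv")
    wt(cp$installation$effects, d, "effects_installation.tsv")
    wt(cp$running$effects, d, "effects_running.tsv")
    wt(cp$delta, d, "delta.tsv")
    cp
  })

  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    config = config,
    config_md5 = unname(tools::md5sum(cfg_file)),
    seed = seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("emfkit")),
    stages = c("simulate", "emf", "diversity", "screen", "activity",
               "attribute", "sem")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res <- list(study = study, emf = emf_res, diversity = div_res,
              screen = screen_res, activity = act_res,
              attribution = attr_res, sem = sem_res, out_dir = out_dir)
  write_report(out_dir, res)
  invisible(res)
}

#' Score planted-truth recovery for a completed synthetic run
#'
#' @param res Result list from [run_pipeline()] on a simulated study.
#' @return List with per-domain indicator sensitivity and false discovery
#'   rate, and the mean absolute error of the path coefficients obtained by
#'   refitting the generating DAG to the simulated driver layer.
#' @export
recovery_scores <- function(res) {
  truth <- res$study$truth
  if (is.null(truth)) return(NULL)
  ind <- lapply(c(prokaryote = "prokaryote", fungus = "fungus"), function(d) {
    iv <- res$screen[[d]]$indval
    called <- iv$taxon_id[iv$is_indicator]
    planted <- truth$indicators[[d]]$taxon_id
    tp <- length(intersect(called, planted))
    list(sensitivity = if (length(planted)) tp / length(planted) else NA,
         fdr = if (length(called)) 1 - tp / length(called) else 0,
         n_called = length(called), n_planted = length(planted))
  })
  tr <- truth$sem
  dag <- dag_spec(tr[c("from", "to")])
  fit <- fit_psem(dag, res$study$drivers)
  key <- function(d) paste(d$from, d$to)
  m <- match(key(fit$coefficients), key(tr))
  sem_err <- mean(abs(fit$coefficients$beta - tr$beta[m]), na.rm = TRUE)
  list(indicators = ind, sem_mean_abs_beta_error = sem_err)
}

#' Write a Markdown report for a completed run
#'
#' Summarises the run's result surfaces: effect sizes per EMF index and
#' category, diversity-EMF fits, screen summaries, attribution tables and
#' the SEM comparison; adds truth-recovery scores when the run was
#' simulated.
#'
#' @param run_dir Run directory (for locating/naming outputs).
#' @param res Result list from [run_pipeline()]; if `NULL`, the function
#'   checks the directory for complete stage outputs and errors listing
#'   missing stages.
#' @return Path of the report file, invisibly.
#' @export
write_report <- function(run_dir, res = NULL) {
  stages <- c("emf", "diversity", "screen", "activity", "attribute", "sem")
  if (is.null(res)) {
    missing <- stages[!dir.exists(file.path(run_dir, stages))]
    if (length(missing))
      stop("incomplete run; missing stages: ", paste(missing, collapse = ", "))
    stop("re-run via run_pipeline() to regenerate the report from results")
  }
  md <- c("# Pipeline report", "",
          sprintf("Output directory: `%s`", run_dir), "")
  tab <- function(df, digits = 3) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, digits))
    c(paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")),
      "")
  }
  md <- c(md, "## Annual effect sizes (EMF indices and categories)", "",
          tab(res$emf$effects))
  md <- c(md, "## Kruskal-Wallis group comparisons", "", tab(res$emf$kruskal))
  md <- c(md, "## Diversity-EMF single-predictor fits", "",
          tab(res$attribution$scan))
  screen_sum <- do.call(rbind, lapply(c("prokaryote", "fungus"), function(d) {
    s <- res$screen[[d]]
    data.frame(domain = d,
               n_filtered = nrow(s$filtered),
               n_indicator = sum(s$indval$is_indicator),
               n_keystone = sum(s$topology$is_keystone),
               n_abundant = sum(s$abundance$class == "abundant"),
               n_rare = sum(s$abundance$class == "rare"))
  }))
  md <- c(md, "## Taxa screen summary", "", tab(screen_sum))
  md <- c(md, "## Variance partitioning (components of adjusted R2)", "",
          tab(data.frame(component = names(res$attribution$vpa$components),
                         fraction = unname(res$attribution$vpa$components))))
  md <- c(md, "## LMG relative importance", "",
          tab(data.frame(variable = names(res$attribution$lmg),
                         share = unname(res$attribution$lmg))))
  md <- c(md, "## Partial correlations with EMF", "", tab(res$attribution$pcor))
  md <- c(md, "## Random-forest importance", "", tab(res$attribution$rf))
  md <- c(md, "## Piecewise SEM period contrast", "", tab(res$sem$delta))
  md <- c(md, sprintf(
    "Installation: Fisher's C = %.2f (df %d, p = %.3f); running: C = %.2f (df %d, p = %.3f)",
    res$sem$installation$fisher_c, res$sem$installation$df,
    res$sem$installation$model_p, res$sem$running$fisher_c,
    res$sem$running$df, res$sem$running$model_p), "")
  rec <- recovery_scores(res)
  if (!is.null(rec)) {
    rec_tab <- do.call(rbind, lapply(names(rec$indicators), function(d)
      data.frame(domain = d,
                 sensitivity = rec$indicators[[d]]$sensitivity,
                 fdr = rec$indicators[[d]]$fdr)))
    md <- c(md, "## Truth recovery (simulated run)", "", tab(rec_tab),
            sprintf("Mean |path coefficient error| refitting the generating DAG: %.3f",
                    rec$sem_mean_abs_beta_error), "")
  }
  path <- file.path(run_dir, "report.md")
  writeLines(md, path)
  invisible(path)
}
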