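#' Microbial activity indices from raw measurements
#'
#' Derives the two metabolic-efficiency ratios from raw plot-level
#' measurements: the metabolic quotient `qCO2 = c_min / mbc` (carbon
#' mineralization over microbial biomass carbon; per day when `c_min` is a
#' daily rate and both carbon pools share units) and `Cmic/Corg = 100 *
#' mbc / (1000 * soc)` in percent, converting MBC (ug C per g soil, i.e. mg
#' per kg) against SOC (g C per kg soil).
#'
#' @param raw data.frame with columns `plot_id`, `copies_pro`,
#'   `copies_fun`, `mbc` (ug C/g), `soc` (g C/kg), `c_min` (ug CO2-C/g/day).
#' @return data.frame: the raw columns plus `qco2` and `cmic_corg`.
#' @export
compute_activity_indices <- function(raw) {
  need <- c("plot_id", "copies_pro", "copies_fun", "mbc", "soc", "c_min")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  num <- raw[setdiff(need, "plot_id")]
  if (any(vapply(num, function(x) any(!is.finite(x) | x < 0), logical(1))))
    stop("all activity measurements must be finite and non-negative")
  bad <- raw$plot_id[raw$mbc <= 0 | raw$soc <= 0]
  if (length(bad))
    stop(sprintf("zero denominator (mbc or soc) in plot(s): %s",
                 paste(bad, collapse = ", ")))
  out <- raw[need]
  out$qco2 <- raw$c_min / raw$mbc
  out$cmic_corg <- 100 * raw$mbc / (1000 * raw$soc)
  out
}

#' Microbial activity composite (PC1 of the activity indices)
#'
#' Gene copy numbers are log10-transformed (they span orders of magnitude),
#' all columns z-scored, and the metabolic quotient enters with reversed
#' sign so that a higher composite means higher activity (a declining
#' quotient indicates improved carbon-use efficiency). PC1 is sign-anchored
#' to a positive loading on microbial biomass carbon.
#'
#' @param indices Output of [compute_activity_indices()].
#' @param reverse_qco2 Reverse the quotient's sign (default `TRUE`).
#' @return List: `scores` (PC1 per plot, named), `loadings`,
#'   `var_explained`, plus the full PCA score matrix as `all_scores`.
#' @export
activity_composite <- function(indices, reverse_qco2 = TRUE) {
  if (nrow(indices) < 3) stop("need at least 3 plots")
  mat <- cbind(
    copies_pro = log10(indices$copies_pro),
    copies_fun = log10(indices$copies_fun),
    mbc = indices$mbc,
    qco2 = if (reverse_qco2) -indices$qco2 else indices$qco2,
    cmic_corg = indices$cmic_corg
  )
  rownames(mat) <- indices$plot_id
  pc <- pca_anchored(mat, anchor = "mbc")
  list(scores = setNames(pc$scores[, 1], indices$plot_id),
       loadings = pc$loadings, var_explained = pc$var_explained,
       all_scores = pc$scores)
}
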