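#!/usr/bin/env Rscript
# Taxonomic (richness), phylogenetic (Faith's PD), functional (Gower FDis
# for plants, guild richness for microbes) alpha diversity per domain.
suppressMessages(library(emfkit))
study <- read_study("results/study")
dir.create("results/diversity", showWarnings = FALSE)
for (dom in names(study$communities)) {
  cm <- study$communities[[dom]]
  dv <- diversity_profile(cm$counts, tree = study$trees[[dom]],
                          traits = if (dom == "plant") study$traits,
                          guild_map = if (!is.null(cm$taxonomy$guild)) cm$taxonomy)
  write.table(dv, sprintf("results/diversity/diversity_%s.tsv", dom),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%-11s mean richness %.1f, mean PD %.2f\n", dom,
              mean(dv$richness), mean(dv$faith_pd)))
}
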