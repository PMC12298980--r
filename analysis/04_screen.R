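#!/usr/bin/env Rscript
# Screen microbial taxa into the four categories: indicator (IndVal with
# permutation test), network keystone (Zi/Pi), abundant and rare.
suppressMessages(library(emfkit))
study <- read_study("results/study")
dir.create("results/screen", showWarnings = FALSE)
for (dom in c("prokaryote", "fungus")) {
  ct <- filter_asvs(study$communities[[dom]]$counts)
  iv <- indval(ct, study$metadata$group, n_perm = 999, seed = 1)
  ab <- classify_abundance(study$communities[[dom]]$counts)
  net <- suppressWarnings(build_network(ct))
  topo <- zi_pi(net, detect_modules(net))
  for (nm in c("indicators", "abundance", "topology"))
    write.table(switch(nm, indicators = iv, abundance = ab, topology = topo),
                sprintf("results/screen/%s_%s.tsv", nm, dom),
                sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%-11s %d/%d taxa pass filter; %d indicators, %d keystones, %d abundant, %d rare\n",
              dom, nrow(ct), nrow(study$communities[[dom]]$counts),
              sum(iv$is_indicator), sum(topo$is_keystone),
              sum(ab$class == "abundant"), sum(ab$class == "rare")))
}
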