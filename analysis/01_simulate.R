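#!/usr/bin/env Rscript
# Generate the default synthetic study: 3 habitat groups (undisturbed Y0,
# one year after installation Y1, six years Y6) x 6 plots, 23 ecosystem
# functions in 6 categories, prokaryotic/fungal/plant communities with
# planted indicator taxa, phylogenies, traits and activity measurements.
suppressMessages(library(emfkit))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

study <- generate_study(study_design(seed = seed))
write_study(study, "results/study")
cat("Wrote synthetic study to results/study (seed", seed, ")\n")
cat(sprintf("Functions: %d plots x %d functions\n",
            nrow(study$functions), ncol(study$functions)))
for (d in names(study$communities))
  cat(sprintf("%-11s %d taxa, %d planted indicators\n", d,
              nrow(study$communities[[d]]$counts),
              nrow(study$communities[[d]]$truth$indicators)))
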