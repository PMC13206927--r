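#!/usr/bin/env Rscript
# Stage 1: materialize the synthetic study workspace.
#
# Builds everything downstream stages consume: two target gene lists with
# a planted 21-gene intersection (164- and 865-gene lists, the shape of a
# typical compound-target vs disease-gene comparison), a GMT annotation
# with one strongly enriched planted term, and a three-arm biomarker
# panel (control / toxicant / pretreatment+toxicant) with four replicates
# per cell and 10% Gaussian noise.

library(ibrtox)

seed <- 20260926
ws <- "results/workspace"
files <- write_fixtures(ws, seed = seed)

cat("Workspace written under", ws, "\n")
for (nm in names(files)) cat(sprintf("  %-10s %s\n", nm, files[[nm]]))

tb <- read.delim(files[["panel"]])
cat("\nPanel:", length(unique(tb$group)), "groups x",
    length(unique(tb$biomarker)), "biomarkers x",
    max(tb$replicate), "replicates\n")
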