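#!/usr/bin/env Rscript
# Stage 4: Integrated Biomarker Response of the three-arm panel.
#
# Chains the full IBR construction — per-biomarker standardization of the
# group means (sample SD), direction signing so larger always means a
# larger treatment response, translation by |min| to non-negative radar
# radii, and the star-polygon area as the per-group index. Higher index =
# greater overall damage; the pretreatment arm should land between the
# control and the full-dose toxicant arm.

library(ibrtox)

ws <- "results/workspace"
panel <- build_panel(read.delim(file.path(ws, "panel.tsv")),
                     read.delim(file.path(ws, "directions.tsv")))
res <- compute_ibr(panel, sd_mode = "sample", min_scope = "biomarker")

cat("group means (X):\n"); print(round(panel$X, 3))
cat("\nradar radii (S):\n"); print(round(res$S, 3))
cat("\nIBR index per group:\n"); print(round(res$ibr_index, 3))

long <- data.frame(group = rep(rownames(res$S), ncol(res$S)),
                   biomarker = rep(colnames(res$S), each = nrow(res$S)),
                   Y = as.vector(res$Y), Z = as.vector(res$Z),
                   S = as.vector(res$S))
write.table(long, "results/ibr_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(as.list(res$ibr_index), "results/ibr_index.json",
                     auto_unbox = TRUE, digits = NA)
write_radar_svg(res, "results/radar.svg")
cat("\nwrote results/ibr_scores.tsv, results/ibr_index.json, results/radar.svg\n")
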