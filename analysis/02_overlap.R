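#!/usr/bin/env Rscript
# Stage 2: intersect the compound-target and disease gene lists.
#
# Reports the two-set Venn partition and the one-sided hypergeometric
# probability of an overlap at least this large in a 20000-gene
# background. With the planted fixture the intersection is exactly 21
# genes; the expected overlap of random 164- and 865-gene sets in that
# universe is ~7, so the planted signal tests clearly enriched.

library(ibrtox)

ws <- "results/workspace"
a <- read_gene_list(file.path(ws, "targets_a.txt"))
b <- read_gene_list(file.path(ws, "targets_b.txt"))

summ <- overlap_summary(a, b, n_universe = 20000)
print(summ)

dir.create("results", showWarnings = FALSE)
write.table(summ, "results/overlap.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(intersect_sets(a, b)$symbols, "results/overlap_genes.txt")
cat(sprintf("\n%d shared genes (p = %.3g); written to results/overlap_genes.txt\n",
            summ$both, summ$p_value))
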