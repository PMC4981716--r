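#!/usr/bin/env Rscript
# Transcriptome workflow: bottom-20% expression filter, log2 + per-gene
# standardization, hierarchical clustering into six profiles merged to
# the major clusters by eigengene correlation, eigengene alignment with
# growth rate, and Fisher exact functional enrichment per cluster.

library(photoacclim)

bundle <- "results/synthetic_bundle"
rpkm <- read_expression_matrix(file.path(bundle, "expression_rpkm.tsv"))
ann <- read_units_tsv(file.path(bundle, "annotations.tsv"))
ss <- read_steady_state_table(file.path(bundle, "steady_states.tsv"))

res <- cluster_expression(rpkm, k = 6, merge_r = 0.8)
sizes <- sort(table(res$labels), decreasing = TRUE)
cat(sprintf("%d genes retained (%d filtered, %d constant) in %d major clusters\n",
            length(res$labels), length(res$removed),
            length(res$excluded), length(sizes)))
for (cl in names(sizes))
  cat(sprintf("  cluster %s: %d genes (%.1f%%), eigengene explains %.0f%%\n",
              cl, sizes[[cl]], 100 * sizes[[cl]] / length(res$labels),
              100 * res$variance_explained[[cl]]))

write_units_tsv(data.frame(gene = names(res$labels),
                           cluster = res$labels),
                "results/cluster_labels.tsv")
eg <- data.frame(cluster = rownames(res$eigengenes), res$eigengenes,
                 check.names = FALSE)
write_units_tsv(eg, "results/eigengenes.tsv")

mu <- tapply(ss$mu, ss$Ii, mean)
pheno <- mu[colnames(res$eigengenes)]
cors <- apply(res$eigengenes, 1, correlate_eigengene, phenotype = pheno)
cat("eigengene correlation with growth rate:\n")
print(round(cors, 3))

enr <- enrich_all_clusters(res$labels, ann)
write_units_tsv(enr, "results/enrichment.tsv")
sig <- enr[enr$significant, ]
cat(sprintf("%d significant (cluster, category) pairs at P < 0.05:\n",
            nrow(sig)))
print(sig[, c("cluster", "level", "category", "pct_genes", "ratio",
              "p_value")], digits = 3)
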