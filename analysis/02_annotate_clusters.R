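#!/usr/bin/env Rscript
# Anchor the single-cell clusters of species A to the LCM bulk cell types:
# per-cell correlations, cluster best-hit annotation, one-vs-rest DEGs,
# LCM up-gene calling, and the genes upregulated in both assays
# (the single-cell/LCM intersection).

suppressMessages(library(xylocomp))

dat <- "results/data"
out <- "results"

m <- read_count_matrix(file.path(dat, "ptr_matrix"), species = "ptr")
m <- filter_cells(m, min_umi = 100)
clusters <- read.delim(file.path(dat, "clusters_ptr.tsv"))
clusters <- clusters$cluster[match(cell_ids(m), clusters$cell_id)]
lcm <- read_lcm_profile(file.path(dat, "lcm_tpm.tsv"))

nm <- normalize_counts(m, scale_factor = 1000)
corr <- correlate_cells_to_types(nm, lcm)
ann <- annotate_clusters(corr, clusters)
write.table(ann, file.path(out, "cluster_annotation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("cluster -> LCM cell type best hits:\n")
print(ann[, c("cluster", "cell_type", "mean_r")], row.names = FALSE)

degs <- one_vs_rest_degs(m, clusters, alpha = 0.05, min_lfc = 1)
de_table <- do.call(rbind, lapply(names(degs), function(cl) {
  if (is.null(degs[[cl]]$de)) return(NULL)
  tb <- degs[[cl]]$de$table
  tb$cluster <- cl
  tb[!is.na(tb$p_adjusted) & tb$p_adjusted < 0.05 &
       abs(tb$log2_fc) >= 1, ]
}))
write.table(de_table, file.path(out, "cluster_degs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\n%d DEG records across %d clusters\n",
            nrow(de_table), length(degs)))

lcm_ups <- lapply(setNames(lcm$types, lcm$types), function(ct)
  lcm_up_genes(lcm, ct, min_tpm = 4, min_lfc = 1))
mapping <- setNames(ann$cell_type, ann$cluster)
shared <- scup_lcmup_intersect(lapply(degs, `[[`, "call"), lcm_ups, mapping)
shared_tab <- do.call(rbind, lapply(names(shared), function(cl)
  if (length(shared[[cl]]))
    data.frame(set = cl, gene_id = shared[[cl]])))
write.table(shared_tab, file.path(out, "scup_lcmup_genes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\ngenes upregulated in both assays per terminal cluster:\n")
print(table(shared_tab$set))
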