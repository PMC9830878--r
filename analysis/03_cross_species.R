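#!/usr/bin/env Rscript
# Cross-species comparison on ortholog groups: aggregate gene counts into
# ortholog-group counts, correlate cluster mean profiles between species,
# call best hits and mutual best hits, and assign differentially expressed
# ortholog groups (DEOs) to cluster modules.

suppressMessages(library(xylocomp))

dat <- "results/data"
out <- "results"

map <- read_ortholog_groups(file.path(dat, "groups.txt"))
ms <- list(ptr = read_count_matrix(file.path(dat, "ptr_matrix"), "ptr"),
           egr = read_count_matrix(file.path(dat, "egr_matrix"), "egr"))
cls <- lapply(names(ms), function(sp) {
  cl <- read.delim(file.path(dat, sprintf("clusters_%s.tsv", sp)))
  cl$cluster[match(cell_ids(ms[[sp]]), cl$cell_id)]
})
names(cls) <- names(ms)

om <- lapply(ms, aggregate_orthogroups, map = map)
cat(sprintf("aggregated to %d (ptr) / %d (egr) ortholog groups; %d / %d genes unmapped\n",
            n_genes(om$ptr), n_genes(om$egr),
            length(attr(om$ptr, "unmapped_genes")),
            length(attr(om$egr, "unmapped_genes"))))

cc <- cluster_profile_correlation(om$ptr, om$egr, cls$ptr, cls$egr)
write.table(data.frame(cluster_a = rownames(cc$r), round(cc$r, 4),
                       check.names = FALSE),
            file.path(out, "cluster_correlation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

mbh <- mutual_best_hits(cc)
write.table(mbh$best_a, file.path(out, "best_hits.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\n%d of %d clusters form mutual best-hit pairs:\n",
            nrow(mbh$mutual), nrow(cc$r)))
print(mbh$mutual, row.names = FALSE)

# DEOs from per-cluster one-vs-rest tests on the ortholog matrices; a
# group differential in both species' matching clusters is a DEO
deg_o <- lapply(om, function(o) {
  sp <- o$species
  one_vs_rest_degs(o, cls[[sp]])
})
deo_lists <- lapply(setNames(names(deg_o$ptr), names(deg_o$ptr)),
                    function(cl) {
  both <- intersect(deg_o$ptr[[cl]]$call$up, deg_o$egr[[cl]]$call$up)
  tb <- deg_o$ptr[[cl]]$de$table
  data.frame(group_id = both,
             log2_fc = tb$log2_fc[match(both, tb$gene_id)])
})
modules <- assign_deo_modules(deo_lists,
                              setNames(seq_along(deo_lists),
                                       names(deo_lists)))
write.table(modules, file.path(out, "deo_modules.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\n%d DEOs assigned to %d modules\n", nrow(modules),
            length(unique(modules$module))))
print(table(modules$cluster))
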