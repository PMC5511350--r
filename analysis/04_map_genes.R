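#!/usr/bin/env Rscript
# Stage 4 — promoter-capture Hi-C gene mapping.
#
# Links SE constituents and typical enhancers to the genes whose promoters
# they contact (interaction score >= 5, bait-bait links honoured in both
# directions, bait-to-prey links from a queried bait ignored), buckets
# genes by enhancer connectivity, and exports the per-fragment feature /
# interaction-degree table.

library(mkregmap)

ds <- read_dataset("results/analysis/data")
out <- "results/analysis"
cons <- read.delim(file.path(out, "se_constituents_MK.tsv"),
                   stringsAsFactors = FALSE)

regions <- data.frame(id = paste0("C", seq_len(nrow(cons))),
                      chrom = cons$chrom, start = cons$start,
                      end = cons$end, is_super = cons$is_super,
                      stringsAsFactors = FALSE)
links <- link_regions_to_genes(regions, ds$fragments, ds$baits,
                               ds$interactions, score_min = 5,
                               layout = ds$layout)
write.table(links, file.path(out, "enhancer_gene_links.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("gene links: %d region-gene pairs, %d distinct genes\n",
            nrow(links), length(unique(links$GENE_ID))))
cat(sprintf("genes contacted by SE constituents: %d; by TEs only: %d\n",
            length(unique(links$GENE_ID[links$is_super])),
            length(setdiff(links$GENE_ID[!links$is_super],
                           links$GENE_ID[links$is_super]))))

gl <- links
names(gl)[names(gl) == "region_id"] <- "enhancer_id"
expr <- expression_by_connectivity(ds$genes, gl)
write.table(expr$buckets, file.path(out, "expression_by_connectivity.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
med <- function(comp) stats::median(
  expr$buckets$median_fpkm[expr$buckets$composition == comp])
cat(sprintf("median-of-bucket-median FPKM: SE-only %.1f vs TE-only %.1f (%d unlinked genes)\n",
            med("SE-only"), med("TE-only"), expr$n_unlinked))

feat <- fragment_feature_table(
  ds$fragments, ds$interactions,
  feature_sets = list(ctcf = ds$ctcf, open_chromatin = ds$peaks$MK),
  score_min = 5, layout = ds$layout)
write.table(feat, file.path(out, "fragment_features.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("fragment table: %d fragments, %d with degree > 0\n",
            nrow(feat), sum(feat$degree > 0)))
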