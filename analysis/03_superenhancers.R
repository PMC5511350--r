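#!/usr/bin/env Rscript
# Stage 3 — super-enhancer calling.
#
# Removes enhancers within 1 kb of promoter-like states, stitches the rest
# within 12.5 kb, ranks stitched regions by background-subtracted H3K27ac
# signal and splits SEs from other enhancers where a unit-slope tangent
# touches the scaled rank curve. SE sets of MKs and EBs are compared with
# the 50-percent-of-either-length rule, and SE constituents are traced
# back through progenitor open chromatin.

library(mkregmap)

ds <- read_dataset("results/analysis/data")
out <- "results/analysis"
se <- list()

for (cell in c("MK", "EB")) {
  enh <- ds$enhancers[[cell]][, c("chrom", "start", "end", "name")]
  filt <- filter_promoter_enhancers(enh, ds$promoters, pad = 1000,
                                    layout = ds$layout)
  cat(sprintf("%s: %d enhancer segments, %d after promoter filter\n",
              cell, nrow(enh), nrow(filt)))
  calls <- call_superenhancers(filt, ds$signal[[cell]]$treatment,
                               ds$signal[[cell]]$input,
                               exclude = ds$promoters, max_gap = 12500,
                               layout = ds$layout)
  se[[cell]] <- calls
  cat(sprintf("%s: %d stitched regions -> %d SEs (%d constituents), %d other enhancers (%d TEs)\n",
              cell, nrow(calls$calls), sum(calls$calls$is_super),
              sum(calls$constituents$is_super),
              sum(!calls$calls$is_super),
              sum(!calls$constituents$is_super)))
  tab <- calls$calls
  write.table(tab, file.path(out, paste0("se_calls_", cell, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(calls$constituents,
              file.path(out, paste0("se_constituents_", cell, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

ov <- se_overlap(se$MK$calls[se$MK$calls$is_super, ],
                 se$EB$calls[se$EB$calls$is_super, ],
                 min_frac = 0.5, layout = ds$layout)
cat(sprintf("shared SEs: %d of %d (MK), %d of %d (EB)\n",
            ov$n_shared_a, sum(se$MK$calls$is_super),
            ov$n_shared_b, sum(se$EB$calls$is_super)))

tr <- trace_se_opening(
  se$MK$constituents[se$MK$constituents$is_super, ],
  ds$peaks$MK,
  list(HSC = ds$peaks$HSC, CMP = ds$peaks$CMP, MEP = ds$peaks$MEP),
  pad = 500, layout = ds$layout)
write.table(tr$constituents, file.path(out, "se_opening_trace.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("MK SEs with every constituent open in HSC+CMP+MEP: %d of %d\n",
            sum(tr$regions$fully_open), nrow(tr$regions)))
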