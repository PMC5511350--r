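# One fixture genome exercising every assignment tier. Fragments are
# 10 kb tiles F1..F20 on a 200 kb chromosome; baits carry the genes whose
# TSSs they hold; interactions connect bait F8 ({GTGT}) to prey F14 and to
# bait F6.
assignment_fixture <- function() {
  lay <- genome_layout("chr1", 200000)
  bounds <- seq(0, 200000, by = 10000)
  fragments <- interval_set(rep("chr1", 20), bounds[-21], bounds[-1],
                            name = paste0("F", 1:20), layout = lay)
  genes <- data.frame(
    GENE_ID = c("GEXP", "GLOW", "GPROM", "GTGT", "GB10"),
    CHR = "chr1",
    TSS = c("15001", "35001", "55001", "75001", "95001"),
    FPKM = c(10, 0.5, 5, 8, 2), stringsAsFactors = FALSE)
  promoters <- interval_set("chr1", c(54500, 120000), c(55500, 121000),
                            layout = lay)   # second has no TSS
  enhancers <- interval_set("chr1", 130000, 131000, layout = lay)
  baits <- make_baits(fragments, genes, lay)
  interactions <- data.frame(
    bait_id = c("F8", "F8"), oe_id = c("F14", "F6"), score = c(7, 6),
    stringsAsFactors = FALSE)
  ld <- data.frame(
    SENTINEL_ID = c("v5", "v5", "v6", "v6", "v7"),
    PROXY_ID = c("v5_a", "v5_b", "v6_a", "v6_b", "v7_a"),
    PROXY_CHR = "chr1",
    PROXY_POS = c(55200, 135000, 175000, 135000, 55300),
    R2 = c(1, 0.85, 1, 0.95, 0.82), stringsAsFactors = FALSE)
  res <- assignment_resources(genes, promoters, enhancers, fragments,
                              baits, interactions, ld, lay)
  list(lay = lay, res = res)
}

fixture_variant <- function(id, pos, consequence = "intronic_or_intergenic",
                            vep = "") {
  data.frame(ID = id, CHR = "chr1", POS = pos, TRAIT = "platelet",
             PVAL = 0.5, CONSEQUENCE = consequence, VEP_GENE = vep,
             stringsAsFactors = FALSE)
}
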