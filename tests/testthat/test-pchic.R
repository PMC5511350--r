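# a small fragment grid with two genes and a hand-written interaction set
pchic_fixture <- function() {
  lay <- genome_layout("chr1", 100000)
  bounds <- seq(0, 100000, by = 10000)
  fragments <- interval_set(rep("chr1", 10), bounds[-11], bounds[-1],
                            name = paste0("F", 1:10), layout = lay)
  genes <- data.frame(GENE_ID = c("VWF", "CD9", "GP6"), CHR = "chr1",
                      TSS = c("25001", "45001;46001", "45500"),
                      FPKM = c(12, 3, 0.2), stringsAsFactors = FALSE)
  baits <- make_baits(fragments, genes, lay)   # F3 = {VWF}, F5 = {CD9, GP6}
  inter <- data.frame(
    bait_id = c("F3", "F5", "F5", "F3"),
    oe_id = c("F7", "F7", "F3", "F9"),
    score = c(6, 4, 10, 10), stringsAsFactors = FALSE)
  list(lay = lay, fragments = fragments, genes = genes, baits = baits,
       inter = inter)
}

test_that("regions map to all overlapping fragments in order", {
  fx <- pchic_fixture()
  expect_equal(map_to_fragments(interval_set("chr1", 61000, 61500),
                                fx$fragments, fx$lay), "F7")
  expect_equal(map_to_fragments(interval_set("chr1", 69990, 70010),
                                fx$fragments, fx$lay), c("F7", "F8"))
  expect_error(map_to_fragments(interval_set("chr1", 99000, 120000),
                                fx$fragments, fx$lay), "beyond")

  set.seed(13)
  for (k in 1:100) {
    s <- sample(0:99000, 1)
    reg <- interval_set("chr1", s, s + sample(100:15000, 1))
    reg$end <- pmin(reg$end, 100000)
    exp <- fx$fragments$name[bf_overlap_pairs(reg, fx$fragments)$b_idx]
    expect_equal(map_to_fragments(reg, fx$fragments, fx$lay), exp)
  }
})

test_that("baits annotate fragments with the genes whose TSSs they hold", {
  fx <- pchic_fixture()
  expect_equal(fx$baits$fragment_id, c("F3", "F5"))
  expect_equal(fx$baits$genes, c("VWF", "CD9;GP6"))
})

test_that("interacting_genes applies the threshold and bait rules", {
  fx <- pchic_fixture()
  # prey region: only the score >= 5 interaction contributes
  expect_equal(interacting_genes(interval_set("chr1", 61000, 61500),
                                 fx$fragments, fx$baits, fx$inter,
                                 layout = fx$lay), "VWF")
  # region on bait F3: bait -> prey F9 is not considered,
  # but the bait-bait link (F5, F3) contributes F5's genes
  expect_equal(interacting_genes(interval_set("chr1", 21000, 21500),
                                 fx$fragments, fx$baits, fx$inter,
                                 layout = fx$lay), c("CD9", "GP6"))
  # monotone non-increasing in score_min
  g4 <- interacting_genes(interval_set("chr1", 61000, 61500),
                          fx$fragments, fx$baits, fx$inter, score_min = 4,
                          layout = fx$lay)
  expect_true(all(c("CD9", "GP6", "VWF") %in% g4))
  g7 <- interacting_genes(interval_set("chr1", 61000, 61500),
                          fx$fragments, fx$baits, fx$inter, score_min = 7,
                          layout = fx$lay)
  expect_equal(g7, character())
  # adding an interaction never removes genes
  more <- rbind(fx$inter, data.frame(bait_id = "F5", oe_id = "F7",
                                     score = 9))
  expect_true(all("VWF" %in%
                    interacting_genes(interval_set("chr1", 61000, 61500),
                                      fx$fragments, fx$baits, more,
                                      layout = fx$lay)))
})

test_that("fragment degrees and feature counts match the edge list", {
  fx <- pchic_fixture()
  feats <- list(ctcf = interval_set("chr1", c(100, 62000), c(300, 62100)))
  tab <- fragment_feature_table(fx$fragments, fx$inter, feats,
                                score_min = 5, layout = fx$lay)
  expect_equal(nrow(tab), 10)  # no silent drops
  expect_equal(tab$degree[tab$fragment_id == "F3"], 3)  # F5, F7, F9 at >= 5
  expect_equal(tab$degree[tab$fragment_id == "F7"], 1)
  expect_equal(tab$degree[tab$fragment_id == "F2"], 0)
  expect_equal(tab$n_ctcf[tab$fragment_id == "F1"], 1)
  expect_equal(tab$n_ctcf[tab$fragment_id == "F7"], 1)
  expect_equal(sum(tab$n_ctcf), 2)
  # oracle: count distinct partners over the thresholded edge list
  edges <- fx$inter[fx$inter$score >= 5, ]
  for (f in tab$fragment_id) {
    exp <- length(unique(c(edges$oe_id[edges$bait_id == f],
                           edges$bait_id[edges$oe_id == f])))
    expect_equal(tab$degree[tab$fragment_id == f], exp)
  }
})

test_that("planted cluster regions recover exactly their target genes", {
  ds <- simulate_dataset(sim_config(seed = 5, n_platelet = 10,
                                    n_redcell = 10))
  cl <- ds$truth$clusters
  for (cid in unique(cl$cluster_id)[1:6]) {
    rows <- cl[cl$cluster_id == cid, ]
    reg <- interval_set(rows$chrom[1], min(rows$start) + 10,
                        min(rows$start) + 50)
    got <- interacting_genes(reg, ds$fragments, ds$baits,
                             ds$interactions, score_min = 5,
                             layout = ds$layout)
    exp <- sort(ds$truth$targets$GENE_ID[ds$truth$targets$cluster_id == cid])
    expect_equal(got, exp)
  }
})
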