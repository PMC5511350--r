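# fixture: n regions spaced far apart with a prescribed score each,
# realised as one enhancer per region with matching signal density
score_fixture <- function(scores, width = 1000, spacing = 20000) {
  n <- length(scores)
  lay <- genome_layout("chr1", n * spacing + 100000)
  start <- (seq_len(n) - 1) * spacing + 5000
  enh <- interval_set("chr1", start, start + width, layout = lay)
  treat <- signal_track("chr1", start, start + width, scores / width,
                        layout = lay)
  input <- signal_track("chr1", start, start + width, rep(0, n),
                        layout = lay)
  list(lay = lay, enh = enh, treat = treat, input = input)
}

test_that("promoter filter removes enhancers within the padded zone", {
  lay <- tiny_layout(1)
  enh <- interval_set("chr1", 5000, 6000, layout = lay)
  prom <- interval_set("chr1", 6500, 6600, layout = lay)
  expect_equal(nrow(filter_promoter_enhancers(enh, prom, 1000, lay)), 0)
  expect_equal(nrow(filter_promoter_enhancers(enh, prom, 0, lay)), 1)

  set.seed(19)
  enh50 <- random_intervals(50, lay, max_len = 400)
  prom10 <- random_intervals(10, lay, max_len = 200)
  got <- filter_promoter_enhancers(enh50, prom10, 1000, lay)
  padded <- interval_set(prom10$chrom, pmax(0, prom10$start - 1000),
                         pmin(lay$length[1], prom10$end + 1000),
                         layout = lay)
  keep <- !seq_len(nrow(enh50)) %in% bf_overlap_pairs(enh50, padded)$a_idx
  expect_equal(got$start, enh50$start[keep])
})

test_that("one dominant region is the single super enhancer", {
  fx <- score_fixture(c(rep(1, 19), 100))
  got <- call_superenhancers(fx$enh, fx$treat, fx$input, layout = fx$lay)
  expect_equal(sum(got$calls$is_super), 1)
  expect_equal(got$calls$rank[got$calls$is_super], 1L)
  expect_equal(got$calls$start[got$calls$is_super], 19 * 20000 + 5000)
  expect_equal(got$threshold$score, 1, tolerance = 1e-9)
})

test_that("tangent cutoff equals brute-force scan on random score vectors", {
  set.seed(29)
  for (k in 1:25) {
    scores <- round(rexp(sample(5:40, 1), 1 / 50), 3)
    fx <- score_fixture(scores)
    got <- call_superenhancers(fx$enh, fx$treat, fx$input, layout = fx$lay)
    exp <- bf_tangent_cutoff(scores)
    expect_equal(got$threshold$score, exp$score, tolerance = 1e-6)
    expect_equal(sum(got$calls$is_super),
                 sum(scores > exp$score + 1e-9))
  }
})

test_that("degenerate curves call no SE and warn", {
  fx <- score_fixture(rep(5, 10))
  expect_equal(sum(call_superenhancers(fx$enh, fx$treat, fx$input,
                                       layout = fx$lay)$calls$is_super), 0)
  fx1 <- score_fixture(c(3, 7))
  expect_warning(got <- call_superenhancers(fx1$enh, fx1$treat, fx1$input,
                                            layout = fx1$lay),
                 "fewer than 3")
  expect_false(any(got$calls$is_super))
  fx0 <- score_fixture(rep(0, 5))
  expect_warning(call_superenhancers(fx0$enh, fx0$treat, fx0$input,
                                     layout = fx0$lay), "zero")
  expect_error(call_superenhancers(fx0$enh[0, ], fx0$treat, fx0$input,
                                   layout = fx0$lay), "empty")
})

test_that("partition is conserved, ranked totally and scale-invariant", {
  set.seed(31)
  ds <- simulate_dataset(sim_config(seed = 31, n_platelet = 10,
                                    n_redcell = 10))
  enh <- ds$enhancers$MK[, c("chrom", "start", "end", "name")]
  filt <- filter_promoter_enhancers(enh, ds$promoters, 1000, ds$layout)
  got <- call_superenhancers(filt, ds$signal$MK$treatment,
                             ds$signal$MK$input, exclude = ds$promoters,
                             layout = ds$layout)
  # conservation: every filtered enhancer in exactly one stitched region
  expect_equal(nrow(got$constituents), nrow(filt))
  expect_equal(sum(got$constituents$is_super) +
                 sum(!got$constituents$is_super), nrow(filt))
  # ranks are a permutation, no super region ranks below a non-super one
  expect_setequal(got$calls$rank, seq_len(nrow(got$calls)))
  expect_true(max(got$calls$rank[got$calls$is_super]) <
                min(got$calls$rank[!got$calls$is_super]))
  # common scaling of both tracks leaves the partition unchanged
  sc <- function(tr, f) signal_track(tr$chrom, tr$start, tr$end,
                                     tr$value * f,
                                     scale = attr(tr, "scale"))
  got2 <- call_superenhancers(filt, sc(ds$signal$MK$treatment, 3.7),
                              sc(ds$signal$MK$input, 3.7),
                              exclude = ds$promoters, layout = ds$layout)
  expect_equal(got2$calls$is_super, got$calls$is_super)
  # planted clusters (>= 10x dispersed signal) are exactly the SE set
  sup <- got$calls[got$calls$is_super, ]
  truth_cl <- ds$truth$clusters[ds$truth$clusters$cell %in%
                                  c("MK", "shared"), ]
  spans <- do.call(rbind, lapply(split(truth_cl, truth_cl$cluster_id),
                                 function(cl) data.frame(
                                   chrom = cl$chrom[1],
                                   start = min(cl$start),
                                   end = max(cl$end))))
  expect_equal(nrow(sup), nrow(spans))
  o <- order(match(sup$chrom, ds$layout$chrom), sup$start)
  so <- order(match(spans$chrom, ds$layout$chrom), spans$start)
  expect_equal(sup$start[o], spans$start[so])
  expect_equal(sup$end[o], spans$end[so])
})

test_that("SE sharing follows the either-length 50 percent rule", {
  a <- interval_set("chr1", 0, 10000)
  expect_true(se_overlap(a, interval_set("chr1", 4000, 20000))$a_shared)
  b <- interval_set("chr1", 9000, 40000)
  ov <- se_overlap(a, b)
  expect_false(ov$a_shared)
  expect_false(ov$b_shared)

  set.seed(37)
  lay <- tiny_layout(2, 500000)
  sa <- random_intervals(40, lay, max_len = 20000)
  sb <- random_intervals(40, lay, max_len = 20000)
  got <- se_overlap(sa, sb, layout = lay)
  pairs <- bf_overlap_pairs(sa, sb)
  exp_a <- logical(40); exp_b <- logical(40)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$a_idx[r]; j <- pairs$b_idx[r]
    w <- min(sa$end[i], sb$end[j]) - max(sa$start[i], sb$start[j])
    if (w >= 0.5 * (sa$end[i] - sa$start[i]) ||
        w >= 0.5 * (sb$end[j] - sb$start[j])) {
      exp_a[i] <- TRUE; exp_b[j] <- TRUE
    }
  }
  expect_equal(got$a_shared, exp_a)
  expect_equal(got$b_shared, exp_b)
})

test_that("SE opening trace flags fully-progenitor-open regions", {
  lay <- tiny_layout(1, 200000)
  cons <- data.frame(id = c("SE1", "SE1", "SE2"),
                     chrom = "chr1", start = c(1000, 5000, 50000),
                     end = c(2000, 6000, 51000), stringsAsFactors = FALSE)
  term <- interval_set("chr1", c(900, 5100, 49900), c(2100, 5900, 51100),
                       layout = lay)
  all_prog <- interval_set("chr1", c(950, 5050), c(2050, 5950),
                           layout = lay)
  prog <- list(HSC = all_prog, CMP = all_prog, MEP = all_prog)
  tr <- trace_se_opening(cons, term, prog, pad = 500, layout = lay)
  expect_true(tr$regions$fully_open[tr$regions$id == "SE1"])
  # SE2's peak overlaps no progenitor peak anywhere
  expect_false(tr$regions$fully_open[tr$regions$id == "SE2"])
  # drop one constituent's progenitor support: SE1 no longer fully open
  prog1 <- list(HSC = interval_set("chr1", 950, 2050, layout = lay),
                CMP = all_prog, MEP = all_prog)
  tr2 <- trace_se_opening(cons, term, prog1, pad = 500, layout = lay)
  expect_false(tr2$regions$fully_open[tr2$regions$id == "SE1"])
})

test_that("expression buckets by connectivity with sort-oracle medians", {
  genes <- data.frame(GENE_ID = paste0("G", 1:6), CHR = "chr1",
                      TSS = "100", FPKM = c(5, 50, 2, 8, 80, 0.4),
                      stringsAsFactors = FALSE)
  links <- data.frame(
    GENE_ID = c(rep("G1", 5), rep("G2", 5), "G3", "G4", "G4", "G5"),
    enhancer_id = c(paste0("t", 1:5), paste0("s", 1:5), "t9", "t7", "s9",
                    "s2"),
    is_super = c(rep(FALSE, 5), rep(TRUE, 5), FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  got <- expression_by_connectivity(genes, links)
  b <- got$buckets
  expect_equal(b$composition[b$n_enhancers == 5 & b$median_fpkm == 5],
               "TE-only")
  expect_equal(b$composition[b$n_enhancers == 5 & b$median_fpkm == 50],
               "SE-only")
  expect_equal(b$composition[b$n_enhancers == 2], "mixed")
  expect_equal(got$n_unlinked, 1)
  # medians equal explicit per-bucket sorts
  one_se <- sort(c(80))
  expect_equal(b$median_fpkm[b$n_enhancers == 1 & b$composition == "SE-only"],
               one_se[ceiling(length(one_se) / 2)])
})
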