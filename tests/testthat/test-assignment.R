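test_that("each tier fires on its dedicated fixture with the right genes", {
  fx <- assignment_fixture()
  check <- function(v, tier, genes) {
    got <- assign_variant(v, fx$res)
    expect_equal(got$tier, tier, info = v$ID)
    expect_equal(got$genes, genes, info = v$ID)
  }
  check(fixture_variant("v1", 15600, "exonic_or_splice", "GEXP"),
        "coding", "GEXP")
  check(fixture_variant("v2", 55200), "promoter", "GPROM")
  check(fixture_variant("v3", 130500, "exonic_or_splice", "GEXP"),
        "enhancer_plus_bait", c("GEXP", "GTGT"))
  check(fixture_variant("v4", 135000), "fragment_interaction", "GTGT")
  check(fixture_variant("v5", 165000), "ld_r2_1", "GPROM")
  check(fixture_variant("v6", 166000), "ld_r2_09", "GTGT")
  check(fixture_variant("v7", 167000), "ld_r2_08", "GPROM")
  check(fixture_variant("v8", 85000), "bait_10kb", c("GB10", "GTGT"))
  check(fixture_variant("v9", 185000), "unassigned", character())
})

test_that("earlier tiers pre-empt later ones on multi-tier fixtures", {
  fx <- assignment_fixture()
  # expressed exonic variant inside a promoter: coding wins
  got <- assign_variant(fixture_variant("v10", 55200, "exonic_or_splice",
                                        "GPROM"), fx$res)
  expect_equal(got$tier, "coding")
  # unexpressed exonic variant in a promoter: falls through to promoter,
  # and takes the promoter gene, not its own
  got <- assign_variant(fixture_variant("v11", 55300, "exonic_or_splice",
                                        "GLOW"), fx$res)
  expect_equal(got$tier, "promoter")
  expect_equal(got$genes, "GPROM")
  # promoter hit on an interacting fragment: promoter precedes interaction
  got <- assign_variant(fixture_variant("v12", 55400), fx$res)
  expect_equal(got$tier, "promoter")
  # unexpressed exonic variant in an enhancer keeps gene and adds baits
  got <- assign_variant(fixture_variant("v13", 130600, "exonic_or_splice",
                                        "GLOW"), fx$res)
  expect_equal(got$tier, "enhancer_plus_bait")
  expect_equal(got$genes, c("GLOW", "GTGT"))
  # a promoter segment without any TSS assigns nothing
  got <- assign_variant(fixture_variant("v15", 120500), fx$res)
  expect_equal(got$tier, "unassigned")
  # r^2 = 1 level success stops the cascade: the 0.85 proxy of v5 would
  # have added GTGT
  got <- assign_variant(fixture_variant("v5", 165000), fx$res)
  expect_equal(got$proxies, "v5_a")
  expect_false("GTGT" %in% got$genes)
})

test_that("a VEP gene without FPKM warns and is treated as unexpressed", {
  fx <- assignment_fixture()
  expect_warning(
    got <- assign_variant(fixture_variant("v14", 185500,
                                          "exonic_or_splice", "GHOST"),
                          fx$res),
    "GHOST")
  expect_equal(got$tier, "unassigned")
})

test_that("assign_all summarises tiers, nearest classes and distances", {
  fx <- assignment_fixture()
  vars <- rbind(fixture_variant("v1", 15600, "exonic_or_splice", "GEXP"),
                fixture_variant("v2", 55200),
                fixture_variant("v4", 135000),
                fixture_variant("v9", 185000))
  got <- assign_all(vars, fx$res)
  expect_equal(unname(got$summary$tier_counts[c("coding", "promoter",
                                                "fragment_interaction",
                                                "unassigned")]),
               rep(1L, 4), ignore_attr = TRUE)
  r <- got$results
  # v1's assigned gene is also its nearest gene
  expect_equal(r$nearest_class[r$ID == "v1"], "nearest_only")
  # v4 sits nearest GB10 (95001) but is assigned distal GTGT (75001)
  expect_equal(r$nearest_class[r$ID == "v4"], "distal_only")
  expect_equal(r$median_assigned_dist[r$ID == "v4"],
               abs(135000 - 75001))
  expect_true(is.na(r$nearest_class[r$ID == "v9"]))
  # median over all (variant, gene) distances equals a direct recompute
  dists <- c(abs(15600 - 15001), abs(55200 - 55001), abs(135000 - 75001))
  expect_equal(got$summary$median_assigned_distance, median(dists))
})

test_that("adding an interaction can only move variants toward assignment", {
  fx <- assignment_fixture()
  v <- fixture_variant("v9", 185000)
  expect_equal(assign_variant(v, fx$res)$tier, "unassigned")
  res2 <- fx$res
  # rebuild resources with an extra interaction reaching v9's fragment
  fx2 <- assignment_fixture()
  genes <- fx2$res$genes
  inter2 <- data.frame(bait_id = c("F8", "F8", "F8"),
                       oe_id = c("F14", "F6", "F19"), score = c(7, 6, 8),
                       stringsAsFactors = FALSE)
  res2 <- assignment_resources(
    genes, interval_set("chr1", c(54500, 120000), c(55500, 121000)),
    interval_set("chr1", 130000, 131000),
    fx2$res$fragments, make_baits(fx2$res$fragments, genes, fx2$lay),
    inter2, fx2$res$ld, fx2$lay)
  got <- assign_variant(v, res2)
  expect_equal(got$tier, "fragment_interaction")
  expect_equal(got$genes, "GTGT")
})

# realize a 2x2 table as intervals and point variants
enrichment_from_counts <- function(a, b, cc, d) {
  n_se <- a + b; n_te <- cc + d
  se <- if (n_se > 0) {
    s <- (seq_len(n_se) - 1) * 1000
    interval_set(rep("chr1", n_se), s, s + 100)
  } else interval_set(character(), numeric(), numeric())
  te <- if (n_te > 0) {
    s <- 1e6 + (seq_len(n_te) - 1) * 1000
    interval_set(rep("chr1", n_te), s, s + 100)
  } else interval_set(character(), numeric(), numeric())
  pos <- c(if (a > 0) (seq_len(a) - 1) * 1000 + 50,
           if (cc > 0) 1e6 + (seq_len(cc) - 1) * 1000 + 50)
  variants <- data.frame(ID = character(), CHR = character(),
                         POS = numeric(), TRAIT = character(),
                         PVAL = numeric(), CONSEQUENCE = character(),
                         VEP_GENE = character(), stringsAsFactors = FALSE)
  if (length(pos)) {
    variants <- data.frame(ID = paste0("v", seq_along(pos)), CHR = "chr1",
                           POS = pos + 1, TRAIT = "platelet", PVAL = 0.5,
                           CONSEQUENCE = "intronic_or_intergenic",
                           VEP_GENE = "", stringsAsFactors = FALSE)
  }
  se_te_variant_enrichment(variants, se, te)
}

test_that("odds ratio follows the closed form and degenerate margins", {
  got <- enrichment_from_counts(5, 95, 10, 890)
  expect_equal(unname(as.vector(t(got$table))), c(5, 95, 10, 890))
  expect_equal(got$odds_ratio, (5 * 890) / (95 * 10))
  deg <- enrichment_from_counts(0, 7, 0, 11)
  expect_true(is.na(deg$odds_ratio))
  expect_equal(deg$p_value, 1)
})

test_that("exact P matches hypergeometric enumeration on random tables", {
  set.seed(17)
  for (k in 1:40) {
    a <- sample(0:25, 1); b <- sample(0:25, 1)
    cc <- sample(0:25, 1); d <- sample(0:25, 1)
    if (a + cc == 0 || b + d == 0 || a + b == 0 || cc + d == 0) next
    got <- enrichment_from_counts(a, b, cc, d)
    expect_equal(got$p_value, bf_fisher_two_sided(a, b, cc, d),
                 tolerance = 1e-12, info = paste(a, b, cc, d))
  }
})
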