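perm_variants <- function(pvals, pos = seq_along(pvals) * 1000,
                          trait = rep("platelet", length(pvals))) {
  data.frame(ID = sprintf("v%02d", seq_along(pvals)), CHR = "chr1",
             POS = pos, TRAIT = trait, PVAL = pvals,
             CONSEQUENCE = "intronic_or_intergenic", VEP_GENE = "",
             stringsAsFactors = FALSE)
}

test_that("circular_shift rotates forward and composes as a group", {
  p <- c(.001, .5, .7, .9, .02)
  expect_equal(circular_shift(p, 2), c(.9, .02, .001, .5, .7))
  expect_equal(circular_shift(p, 0), p)
  q <- circular_shift(p, 4)
  for (k in 1:4) q <- circular_shift(q, 1)
  expect_equal(q, circular_shift(p, 3))  # 4 + 4 = 8 = 3 mod 5
  expect_error(circular_shift(p, 5), "range")
  # rotation preserves the multiset and the circular gap structure of
  # significant entries
  sig <- function(x) which(x < 0.05)
  gaps <- function(idx, n) sort(diff(c(idx, idx[1] + n)))
  r <- circular_shift(p, 3)
  expect_equal(sort(r), sort(p))
  expect_equal(gaps(sig(r), 5), gaps(sig(p), 5))
})

test_that("the 5-variant worked example gives empirical P 0.2", {
  lay <- genome_layout("chr1", 10000)
  v <- perm_variants(c(.2, .2, .2, .001, .2))
  region <- interval_set("chr1", 3500, 4500)  # covers only position 4000
  got <- circular_permutation_test(v, region, lay, mode = "count",
                                   sig_threshold = 0.01,
                                   exhaustive = TRUE)
  expect_equal(got$observed, 1)
  expect_equal(got$rank, 1)
  expect_equal(got$p_empirical, 0.2)
})

test_that("a region covering every variant gives empirical P 1", {
  lay <- genome_layout("chr1", 10000)
  v <- perm_variants(c(.001, .2, .03, .5, .2, .9))
  region <- interval_set("chr1", 0, 10000)
  for (m in c("count", "hypergeom_tail", "trait_contrast")) {
    got <- circular_permutation_test(v, region, lay, mode = m,
                                     sig_threshold = 0.05,
                                     exhaustive = TRUE)
    expect_equal(got$p_empirical, 1)
  }
})

test_that("dataset_statistic matches definitions and enumeration", {
  # count: one significant foreground variant inside the region
  mem <- c(FALSE, FALSE, FALSE, TRUE, FALSE)
  expect_equal(dataset_statistic(c(.2, .2, .2, .001, .2), mem,
                                 fg = rep(TRUE, 5), mode = "count",
                                 sig_threshold = 0.01), 1)
  # hypergeometric tail at zero draws is 1
  expect_equal(dataset_statistic(rep(0.9, 5), mem, fg = rep(TRUE, 5),
                                 mode = "hypergeom_tail",
                                 sig_threshold = 0.01), 1)
  # N = 20 foreground, 5 in region, 4 significant, 3 of them inside:
  # P(X >= 3) by explicit enumeration of the hypergeometric pmf
  mem20 <- c(rep(TRUE, 5), rep(FALSE, 15))
  p20 <- c(rep(1e-9, 3), rep(0.9, 2), 1e-9, rep(0.9, 14))
  got <- dataset_statistic(p20, mem20, fg = rep(TRUE, 20),
                           mode = "hypergeom_tail", sig_threshold = 5e-8)
  enum <- sum(vapply(3:4, function(x)
    choose(5, x) * choose(15, 4 - x), 0)) / choose(20, 4)
  expect_equal(got, enum, tolerance = 1e-12)
})

test_that("exhaustive mode equals the brute-force oracle for n <= 12", {
  set.seed(43)
  lay <- genome_layout("chr1", 100000)
  for (rep in 1:8) {
    n <- sample(5:12, 1)
    pv <- signif(runif(n), 4)
    pv[sample.int(n, sample(1:3, 1))] <- 1e-9
    trait <- sample(c("platelet", "red_cell"), n, replace = TRUE)
    pos <- seq_len(n) * 1000
    mem <- runif(n) < 0.4
    v <- perm_variants(pv, pos, trait)
    region <- if (any(mem)) {
      interval_set(rep("chr1", sum(mem)), pos[mem] - 10, pos[mem] + 10)
    } else interval_set("chr1", 90000, 90010)
    for (m in c("count", "hypergeom_tail", "trait_contrast")) {
      got <- circular_permutation_test(v, region, lay, mode = m,
                                       sig_threshold = 5e-8,
                                       exhaustive = TRUE)
      exp <- bf_exhaustive_test(pv, mem, trait == "platelet",
                                trait == "red_cell", m, 5e-8)
      expect_equal(got$observed, exp$observed, tolerance = 1e-12)
      expect_equal(sort(got$shifted), sort(exp$shifted),
                   tolerance = 1e-12)
      expect_equal(got$rank, exp$rank)
      expect_equal(got$p_empirical, exp$p_empirical, tolerance = 1e-12)
    }
  }
})

test_that("random-offset runs are reproducible under a seed", {
  lay <- genome_layout("chr1", 100000)
  set.seed(47)
  v <- perm_variants(signif(runif(50), 4), seq_len(50) * 1000,
                     sample(c("platelet", "red_cell"), 50, replace = TRUE))
  v$PVAL[c(3, 17, 30)] <- 1e-9
  region <- interval_set("chr1", 10000, 30000)
  a <- circular_permutation_test(v, region, lay, n_shifts = 500, seed = 9)
  b <- circular_permutation_test(v, region, lay, n_shifts = 500, seed = 9)
  expect_identical(a, b)
  expect_true(a$p_empirical > 0)
  expect_error(circular_permutation_test(v[1:2, ], region, lay),
               "at least 3")
})
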