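#' Prepare the resource bundle for variant-to-gene assignment
#'
#' Precomputes the lookups the tiered assignment walks: padded promoter
#' segments with the genes whose TSSs they contain, a per-fragment map of
#' interacting bait genes at the score threshold, and bait fragments padded
#' for the proximity fallback.
#'
#' @param genes Gene table (see [read_genes()]).
#' @param promoters Interval set: promoter, weak-promoter and
#'   bivalent-promoter state segments.
#' @param enhancers Interval set of enhancer-state segments.
#' @param fragments Fragment interval set (`name` ids).
#' @param baits Bait table from [make_baits()].
#' @param interactions Interaction table.
#' @param ld LD table (see [read_ld()]).
#' @param layout A [genome_layout()].
#' @param score_min Interaction score threshold (default 5, inclusive).
#' @param fpkm_min Expression floor; genes below it count as not expressed
#'   (default 1).
#' @param promoter_pad Promoter pad in bp (default 1000).
#' @param bait_pad Bait-proximity pad in bp for the fallback (default 10000).
#' @return An `assignment_resources` list used by [assign_all()].
#' @export
assignment_resources <- function(genes, promoters, enhancers, fragments,
                                 baits, interactions, ld, layout,
                                 score_min = 5, fpkm_min = 1,
                                 promoter_pad = 1000, bait_pad = 10000) {
  tt <- gene_tss_table(genes)
  tsspt <- data.frame(chrom = tt$CHR, start = tt$TSS - 1, end = tt$TSS,
                      stringsAsFactors = FALSE)

  prom_pad <- promoters
  if (nrow(prom_pad) > 0) {
    len <- layout$length[match(prom_pad$chrom, layout$chrom)]
    prom_pad$start <- pmax(0, prom_pad$start - promoter_pad)
    prom_pad$end <- pmin(len, prom_pad$end + promoter_pad)
  }
  # genes whose TSS lies inside each padded promoter segment
  ovp <- interval_overlaps(prom_pad, tsspt, layout = layout)
  prom_genes <- vector("list", nrow(prom_pad))
  if (nrow(ovp$pairs) > 0) {
    gl <- tapply(tt$GENE_ID[ovp$pairs$b_idx], ovp$pairs$a_idx,
                 function(g) sort(unique(g)))
    prom_genes[as.integer(names(gl))] <- gl
  }

  # per-fragment interacting bait genes at the threshold
  gl <- bait_gene_list(baits)
  keep <- interactions$score >= score_min
  bait_id <- interactions$bait_id[keep]
  oe_id <- interactions$oe_id[keep]
  frag_genes <- list()
  add <- function(tab, ids, genes_per) {
    for (i in seq_along(ids)) {
      tab[[ids[i]]] <- c(tab[[ids[i]]], genes_per[[i]])
    }
    tab
  }
  frag_genes <- add(frag_genes, oe_id, gl[bait_id])
  sel <- oe_id %in% names(gl)
  frag_genes <- add(frag_genes, bait_id[sel], gl[oe_id[sel]])
  frag_genes <- lapply(frag_genes, function(g) sort(unique(g)))

  bait_rows <- fragments[fragments$name %in% baits$fragment_id, , drop = FALSE]
  bait_pad_iv <- bait_rows
  if (nrow(bait_pad_iv) > 0) {
    len <- layout$length[match(bait_pad_iv$chrom, layout$chrom)]
    bait_pad_iv$start <- pmax(0, bait_pad_iv$start - bait_pad)
    bait_pad_iv$end <- pmin(len, bait_pad_iv$end + bait_pad)
  }
  bait_pad_genes <- bait_gene_list(baits)[bait_rows$name]

  fpkm <- genes$FPKM
  names(fpkm) <- genes$GENE_ID

  structure(list(genes = genes, mean_tss = gene_mean_tss(genes),
                 fpkm = fpkm, fpkm_min = fpkm_min,
                 promoters_padded = prom_pad, prom_genes = prom_genes,
                 enhancers = enhancers, fragments = fragments,
                 frag_genes = frag_genes, bait_padded = bait_pad_iv,
                 bait_pad_genes = bait_pad_genes, ld = ld,
                 layout = layout, score_min = score_min),
            class = "assignment_resources")
}

# per-point annotation shared by sentinels and proxies:
# list of promoter genes, enhancer hit, fragment-interaction genes,
# padded-bait genes for each 1-based position
annotate_points <- function(chrom, pos, res) {
  pts <- data.frame(chrom = chrom, start = pos - 1, end = pos,
                    stringsAsFactors = FALSE)
  validate_intervals(pts, res$layout)
  n <- nrow(pts)
  collect <- function(targets, glist) {
    ov <- interval_overlaps(pts, targets, layout = res$layout)
    out <- vector("list", n)
    if (nrow(ov$pairs) > 0) {
      got <- tapply(ov$pairs$b_idx, ov$pairs$a_idx, function(idx) {
        sort(unique(unlist(glist[idx], use.names = FALSE)))
      })
      out[as.integer(names(got))] <- got
    }
    lapply(out, function(g) if (is.null(g)) character() else g)
  }
  ovf <- interval_overlaps(pts, res$fragments, layout = res$layout)
  fgenes <- vector("list", n)
  if (nrow(ovf$pairs) > 0) {
    got <- tapply(ovf$pairs$b_idx, ovf$pairs$a_idx, function(idx) {
      sort(unique(unlist(res$frag_genes[res$fragments$name[idx]],
                         use.names = FALSE)))
    })
    fgenes[as.integer(names(got))] <- got
  }
  fgenes <- lapply(fgenes, function(g) if (is.null(g)) character() else g)
  list(promoter = collect(res$promoters_padded, res$prom_genes),
       enhancer = interval_overlaps(pts, res$enhancers,
                                    layout = res$layout)$hits,
       fragment = fgenes,
       bait10 = collect(res$bait_padded, res$bait_pad_genes))
}

ASSIGNMENT_TIERS <- c("coding", "promoter", "enhancer_plus_bait",
                      "fragment_interaction", "ld_r2_1", "ld_r2_09",
                      "ld_r2_08", "bait_10kb", "unassigned")

#' Assign every sentinel variant to candidate target genes
#'
#' Walks the tiered decision tree per variant: (1) expressed exonic/splice
#' variants outside enhancers keep their VEP gene (`coding`); (2) remaining
#' variants overlapping a padded promoter containing a TSS take that TSS's
#' gene(s) (`promoter`); (3) exonic variants inside an enhancer segment keep
#' their gene and add the genes of interacting baits
#' (`enhancer_plus_bait`); (4) remaining variants take the genes of baits
#' interacting with their restriction fragment (`fragment_interaction`);
#' failing that, the LD cascade re-runs the non-coding steps on proxies at
#' r^2 = 1, then >= 0.9, then >= 0.8, unioning genes per level
#' (`ld_r2_1` / `ld_r2_09` / `ld_r2_08`); finally, baits within 10 kb
#' contribute their genes (`bait_10kb`); otherwise `unassigned`. Exonic
#' variants whose gene is not expressed (FPKM below the floor) fall through
#' tier 1.
#'
#' @param variants Variant table (see [read_variants()]).
#' @param resources An [assignment_resources()] bundle.
#' @return A list with `results` (one row per variant: `ID`, `tier`,
#'   `genes`, `proxies`, `nearest_gene`, `nearest_class`,
#'   `median_assigned_dist`, `nearest_dist`) and `summary` (tier counts,
#'   nearest-gene classification counts, median distances for the
#'   interaction-based and the nearest-gene assignment).
#' @export
assign_all <- function(variants, resources) {
  res <- resources
  n <- nrow(variants)
  ann <- annotate_points(variants$CHR, variants$POS, res)

  ld <- res$ld
  prox_ann <- NULL
  if (!is.null(ld) && nrow(ld) > 0) {
    prox_ann <- annotate_points(ld$PROXY_CHR, ld$PROXY_POS, res)
  }

  one <- function(i) {
    cons <- variants$CONSEQUENCE[i]
    vep <- variants$VEP_GENE[i]
    exonic <- identical(cons, "exonic_or_splice") && nzchar(vep)
    expressed <- FALSE
    if (exonic) {
      f <- res$fpkm[vep]
      if (is.na(f)) {
        warning("no FPKM for VEP gene ", vep, "; treated as not expressed")
        f <- 0
      }
      expressed <- f >= res$fpkm_min
    }
    in_enh <- ann$enhancer[i]
    if (exonic && expressed && !in_enh) {
      return(list(tier = "coding", genes = vep, proxies = character()))
    }
    pg <- ann$promoter[[i]]
    if (length(pg)) {
      return(list(tier = "promoter", genes = pg, proxies = character()))
    }
    if (exonic && in_enh) {
      return(list(tier = "enhancer_plus_bait",
                  genes = sort(unique(c(vep, ann$fragment[[i]]))),
                  proxies = character()))
    }
    fg <- ann$fragment[[i]]
    if (length(fg)) {
      return(list(tier = "fragment_interaction", genes = fg,
                  proxies = character()))
    }
    if (!is.null(prox_ann)) {
      levels_r2 <- c(1, 0.9, 0.8)
      tiers_r2 <- c("ld_r2_1", "ld_r2_09", "ld_r2_08")
      for (k in seq_along(levels_r2)) {
        rows <- which(ld$SENTINEL_ID == variants$ID[i] &
                        ld$R2 >= levels_r2[k])
        if (length(rows) == 0) next
        genes <- character()
        used <- character()
        for (r in rows) {
          g <- prox_ann$promoter[[r]]
          if (length(g) == 0) g <- prox_ann$fragment[[r]]
          if (length(g)) {
            genes <- c(genes, g)
            used <- c(used, ld$PROXY_ID[r])
          }
        }
        if (length(genes)) {
          return(list(tier = tiers_r2[k], genes = sort(unique(genes)),
                      proxies = unique(used)))
        }
      }
    }
    bg <- ann$bait10[[i]]
    if (length(bg)) {
      return(list(tier = "bait_10kb", genes = bg, proxies = character()))
    }
    list(tier = "unassigned", genes = character(), proxies = character())
  }

  assigned <- lapply(seq_len(n), one)

  mt <- res$mean_tss
  nearest <- vapply(seq_len(n), function(i) {
    cand <- mt[mt$CHR == variants$CHR[i], , drop = FALSE]
    if (nrow(cand) == 0) return(NA_character_)
    d <- abs(cand$MEAN_TSS - variants$POS[i])
    cand$GENE_ID[order(d, cand$GENE_ID)][1]
  }, "")
  dist_to <- function(i, gene_ids) {
    idx <- match(gene_ids, mt$GENE_ID)
    d <- abs(mt$MEAN_TSS[idx] - variants$POS[i])
    d[mt$CHR[idx] != variants$CHR[i]] <- NA_real_
    d
  }
  nearest_dist <- vapply(seq_len(n), function(i) {
    if (is.na(nearest[i])) NA_real_ else dist_to(i, nearest[i])
  }, 0)

  tier <- vapply(assigned, `[[`, "", "tier")
  genes_str <- vapply(assigned, function(a) paste(a$genes, collapse = ";"), "")
  proxies_str <- vapply(assigned,
                        function(a) paste(a$proxies, collapse = ";"), "")
  nclass <- vapply(seq_len(n), function(i) {
    g <- assigned[[i]]$genes
    if (length(g) == 0) return(NA_character_)
    has_near <- !is.na(nearest[i]) && nearest[i] %in% g
    if (has_near && length(g) == 1) "nearest_only"
    else if (has_near) "nearest_plus_distal"
    else "distal_only"
  }, "")
  med_dist <- vapply(seq_len(n), function(i) {
    g <- assigned[[i]]$genes
    if (length(g) == 0) return(NA_real_)
    stats::median(dist_to(i, g), na.rm = TRUE)
  }, 0)

  results <- data.frame(ID = variants$ID, CHR = variants$CHR,
                        POS = variants$POS, TRAIT = variants$TRAIT,
                        tier = tier, genes = genes_str,
                        proxies = proxies_str, nearest_gene = nearest,
                        nearest_class = nclass,
                        median_assigned_dist = med_dist,
                        nearest_dist = nearest_dist,
                        stringsAsFactors = FALSE)

  all_dists <- unlist(lapply(seq_len(n), function(i) {
    g <- assigned[[i]]$genes
    if (length(g) == 0) return(numeric())
    dist_to(i, g)
  }))
  summary <- list(
    tier_counts = table(factor(tier, levels = ASSIGNMENT_TIERS)),
    n_assigned = sum(tier != "unassigned"),
    frac_assigned = mean(tier != "unassigned"),
    nearest_class_counts = table(factor(
      nclass, levels = c("nearest_only", "nearest_plus_distal",
                         "distal_only"))),
    median_assigned_distance = stats::median(all_dists, na.rm = TRUE),
    median_nearest_distance = stats::median(nearest_dist, na.rm = TRUE)
  )
  list(results = results, summary = summary)
}

#' Assign a single variant
#'
#' Convenience wrapper around [assign_all()] for one variant row.
#'
#' @param variant One-row variant data.frame.
#' @param resources An [assignment_resources()] bundle.
#' @return A list with `tier`, `genes`, `proxies`.
#' @export
assign_variant <- function(variant, resources) {
  out <- assign_all(variant, resources)$results
  list(tier = out$tier[1],
       genes = if (nzchar(out$genes[1]))
         strsplit(out$genes[1], ";", fixed = TRUE)[[1]] else character(),
       proxies = if (nzchar(out$proxies[1]))
         strsplit(out$proxies[1], ";", fixed = TRUE)[[1]] else character())
}

#' Enrichment of variants in SE constituents versus typical enhancers
#'
#' Builds the 2x2 table of SE constituents and typical enhancers bearing at
#' least one variant versus none (element counting; a base-pair-normalized
#' alternative uses variant counts against kb of element length), and
#' reports the cross-product odds ratio with a two-sided exact
#' (hypergeometric) P-value.
#'
#' @param variants Variant table (positions 1-based).
#' @param se_constituents,typical_enhancers Interval sets.
#' @param layout Optional [genome_layout()].
#' @param by `"element"` (default) or `"bp"`.
#' @return A list with the 2x2 `table`, `odds_ratio` (ad/bc; `NA` when
#'   undefined) and `p_value`.
#' @export
se_te_variant_enrichment <- function(variants, se_constituents,
                                     typical_enhancers, layout = NULL,
                                     by = c("element", "bp")) {
  by <- match.arg(by)
  pts <- data.frame(chrom = variants$CHR, start = variants$POS - 1,
                    end = variants$POS, stringsAsFactors = FALSE)
  hit_se <- interval_overlaps(se_constituents, pts, layout = layout)$hits
  hit_te <- interval_overlaps(typical_enhancers, pts, layout = layout)$hits
  if (by == "element") {
    a <- sum(hit_se); b <- sum(!hit_se)
    c_ <- sum(hit_te); d <- sum(!hit_te)
  } else {
    in_se <- interval_overlaps(pts, se_constituents, layout = layout)$hits
    in_te <- interval_overlaps(pts, typical_enhancers, layout = layout)$hits
    a <- sum(in_se)
    c_ <- sum(in_te & !in_se)
    kb_se <- sum(se_constituents$end - se_constituents$start) / 1000
    kb_te <- sum(typical_enhancers$end - typical_enhancers$start) / 1000
    b <- max(0, round(kb_se) - a)
    d <- max(0, round(kb_te) - c_)
  }
  out <- exact_enrichment_test(a, b, c_, d)
  dimnames(out$table) <- list(c("SE_constituent", "typical_enhancer"),
                              c("with_variant", "without_variant"))
  out
}

#' Cross-product odds ratio and two-sided exact P for a 2x2 table
#'
#' The odds ratio is the plain cross-product ad/bc (`NA` when both products
#' vanish, `Inf` when only the denominator does); the P-value is the
#' two-sided conditional exact (hypergeometric) test. Degenerate margins
#' give P = 1.
#'
#' @param a,b,c_,d Non-negative counts, row-wise: `[[a, b], [c_, d]]`.
#' @return A list with `table`, `odds_ratio`, `p_value`.
#' @export
exact_enrichment_test <- function(a, b, c_, d) {
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE)
  or <- if (b * c_ == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else (a * d) / (b * c_)
  p <- if (sum(tab) == 0 || any(rowSums(tab) == 0) ||
           any(colSums(tab) == 0)) {
    1
  } else {
    stats::fisher.test(tab)$p.value
  }
  list(table = tab, odds_ratio = or, p_value = p)
}
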