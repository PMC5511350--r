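#' Remove enhancers confounded by promoter H3K27ac
#'
#' Drops every enhancer-state segment that overlaps (>= 1 bp) the union of
#' promoter, weak-promoter and bivalent-promoter segments extended by `pad`
#' bp (default 1 kb), so promoter acetylation does not leak into enhancer
#' ranking.
#'
#' @param enhancers Interval set of enhancer-state segments.
#' @param promoter_states Interval set: the union of promoter-like states.
#' @param pad Pad in bp applied to promoter states (default 1000).
#' @param layout A [genome_layout()].
#' @return The surviving enhancers (canonical order preserved).
#' @export
filter_promoter_enhancers <- function(enhancers, promoter_states,
                                      pad = 1000, layout) {
  stopifnot(pad >= 0)
  if (nrow(enhancers) == 0 || nrow(promoter_states) == 0) return(enhancers)
  padded <- promoter_states
  len <- layout$length[match(padded$chrom, layout$chrom)]
  padded$start <- pmax(0, padded$start - pad)
  padded$end <- pmin(len, padded$end + pad)
  hit <- interval_overlaps(enhancers, padded, layout = layout)$hits
  out <- enhancers[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Rank-curve threshold: sort scores ascending, scale rank and score to
# [0, 1], and take the point maximizing x - y (where the unit-slope tangent
# touches the scaled curve). Super regions score strictly above that point.
se_cutoff <- function(scores) {
  n <- length(scores)
  o <- order(scores)
  y <- scores[o]
  x <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0
  rng <- y[n] - y[1]
  yscl <- if (rng > 0) (y - y[1]) / rng else rep(0, n)
  i_star <- which.max(x - yscl)
  list(index = i_star, score = y[i_star])
}

#' Call super enhancers from filtered enhancers and H3K27ac signal
#'
#' Stitches promoter-filtered enhancers lying within `max_gap` of each other
#' (see [merge_within()]), scores every stitched or single region as
#' `max(0, treatment - input)` background-subtracted H3K27ac signal over the
#' region (bases in `exclude` discarded), ranks regions by score, and splits
#' super enhancers from the rest at the point of the ascending scaled
#' rank-score curve where a unit-slope tangent touches. Members of super
#' regions are "SE constituents"; members of the remaining regions are
#' typical enhancers (TEs).
#'
#' @param enhancers Interval set of promoter-filtered enhancers.
#' @param h3k27ac Treatment [signal_track()].
#' @param input_signal Input (control) [signal_track()].
#' @param exclude Optional interval set of bases to discard from scoring
#'   (e.g. promoters, blacklisted regions).
#' @param max_gap Stitching gap in bp (default 12500).
#' @param layout A [genome_layout()].
#' @return A list with
#'   `calls`: data.frame of stitched regions (`id`, `chrom`, `start`, `end`,
#'   `score`, `rank` with 1 = highest score, `is_super`, `n_constituents`);
#'   `constituents`: data.frame mapping each input enhancer to its stitched
#'   region (`id`, `chrom`, `start`, `end`, `is_super`);
#'   `threshold`: list with `index` (on the ascending curve) and `score`.
#' @export
call_superenhancers <- function(enhancers, h3k27ac, input_signal,
                                exclude = NULL, max_gap = 12500, layout) {
  if (nrow(enhancers) == 0) stop("empty enhancer set")
  enhancers <- sort_intervals(enhancers, layout)
  stitched <- merge_within(enhancers, max_gap, layout)
  members <- attr(stitched, "members")
  n <- nrow(stitched)
  score <- vapply(seq_len(n), function(i) {
    reg <- stitched[i, ]
    max(0, signal_sum(h3k27ac, reg, exclude) -
          signal_sum(input_signal, reg, exclude))
  }, 0)

  if (all(score == 0)) {
    warning("all region scores are zero; no super enhancers called")
  }
  degenerate <- n < 3
  if (degenerate) {
    warning("fewer than 3 stitched regions; rank curve degenerate, ",
            "no super enhancers called")
    thr <- list(index = NA_integer_, score = NA_real_)
    is_super <- rep(FALSE, n)
  } else {
    thr <- se_cutoff(score)
    is_super <- score > thr$score
  }
  # descending rank; ties broken by genomic position (earlier = better)
  lv <- chrom_levels(stitched$chrom, layout)
  o <- order(-score, match(stitched$chrom, lv), stitched$start, stitched$end)
  rank <- integer(n)
  rank[o] <- seq_len(n)

  calls <- data.frame(id = sprintf("SE%05d", seq_len(n)),
                      chrom = stitched$chrom, start = stitched$start,
                      end = stitched$end, score = score, rank = rank,
                      is_super = is_super,
                      n_constituents = stitched$n_members,
                      stringsAsFactors = FALSE)
  memb_region <- integer(nrow(enhancers))
  for (i in seq_len(n)) memb_region[members[[i]]] <- i
  constituents <- data.frame(id = calls$id[memb_region],
                             chrom = enhancers$chrom,
                             start = enhancers$start, end = enhancers$end,
                             is_super = is_super[memb_region],
                             stringsAsFactors = FALSE)
  list(calls = calls, constituents = constituents, threshold = thr)
}

#' Compare two super-enhancer sets across cell types
#'
#' A region of `se_a` is shared when some region of `se_b` overlaps it by at
#' least `min_frac` of either region's length (the symmetric, inclusive
#' reading of a 50 percent reciprocal-overlap rule), and vice versa.
#'
#' @param se_a,se_b Interval sets (e.g. `calls[calls$is_super, ]` of two cell
#'   types).
#' @param min_frac Minimum overlapping fraction of either region's length
#'   (default 0.5).
#' @param layout Optional [genome_layout()].
#' @return A list with logical vectors `a_shared`, `b_shared` and counts
#'   `n_shared_a`, `n_shared_b`, `n_a_specific`, `n_b_specific`.
#' @export
se_overlap <- function(se_a, se_b, min_frac = 0.5, layout = NULL) {
  ov <- interval_overlaps(se_a, se_b, layout = layout)
  a_shared <- logical(nrow(se_a))
  b_shared <- logical(nrow(se_b))
  if (nrow(ov$pairs) > 0) {
    ai <- ov$pairs$a_idx
    bi <- ov$pairs$b_idx
    w <- pmin(se_a$end[ai], se_b$end[bi]) - pmax(se_a$start[ai], se_b$start[bi])
    la <- se_a$end[ai] - se_a$start[ai]
    lb <- se_b$end[bi] - se_b$start[bi]
    ok <- w >= min_frac * la | w >= min_frac * lb
    a_shared[unique(ai[ok])] <- TRUE
    b_shared[unique(bi[ok])] <- TRUE
  }
  list(a_shared = a_shared, b_shared = b_shared,
       n_shared_a = sum(a_shared), n_shared_b = sum(b_shared),
       n_a_specific = sum(!a_shared), n_b_specific = sum(!b_shared))
}

#' Trace the progenitor opening of SE constituents
#'
#' Each constituent (padded by `pad` bp) is matched to overlapping terminal
#' open-chromatin peaks; those peaks' progenitor presence patterns (minimum
#' 1 bp overlap, unpadded) are propagated back to the constituent. A super
#' enhancer is flagged fully open in progenitors when every one of its
#' constituents overlaps an open region present in HSCs, CMPs and MEPs.
#'
#' @param constituents Constituent table from [call_superenhancers()]
#'   (column `id` groups constituents by stitched region).
#' @param terminal_open_chromatin Interval set of the terminal cell's
#'   open-chromatin peaks.
#' @param progenitor_peaks Named list with `HSC`, `CMP`, `MEP` interval sets.
#' @param pad Constituent pad in bp (default 500).
#' @param layout A [genome_layout()].
#' @return A list with `constituents` (per-constituent logical columns
#'   `open_terminal`, `HSC`, `CMP`, `MEP`, `full_progenitor`) and `regions`
#'   (per-region `id`, `fully_open`).
#' @export
trace_se_opening <- function(constituents, terminal_open_chromatin,
                             progenitor_peaks, pad = 500, layout) {
  pat <- presence_patterns(terminal_open_chromatin, progenitor_peaks,
                           terminal_open_chromatin, layout)
  padded <- constituents
  len <- layout$length[match(padded$chrom, layout$chrom)]
  padded$start <- pmax(0, padded$start - pad)
  padded$end <- pmin(len, padded$end + pad)
  ov <- interval_overlaps(padded, terminal_open_chromatin, layout = layout)
  nC <- nrow(constituents)
  agg <- function(flag) {
    out <- logical(nC)
    if (nrow(ov$pairs) > 0) {
      got <- tapply(flag[ov$pairs$b_idx], ov$pairs$a_idx, any)
      out[as.integer(names(got))] <- as.logical(got)
    }
    out
  }
  full_peak <- pat$HSC & pat$CMP & pat$MEP
  ctab <- data.frame(constituents,
                     open_terminal = ov$hits,
                     HSC = agg(pat$HSC), CMP = agg(pat$CMP),
                     MEP = agg(pat$MEP),
                     full_progenitor = agg(full_peak),
                     stringsAsFactors = FALSE)
  fully <- tapply(ctab$full_progenitor, ctab$id, all)
  regions <- data.frame(id = names(fully), fully_open = as.logical(fully),
                        stringsAsFactors = FALSE)
  rownames(regions) <- NULL
  list(constituents = ctab, regions = regions)
}

#' Median expression of genes by enhancer connectivity
#'
#' Buckets genes by the number of enhancers their promoters contact and by
#' the composition of those enhancers (TE-only, SE-only, mixed), then
#' reports the median FPKM per bucket. Genes with no links are tallied
#' separately, not silently dropped.
#'
#' @param genes Gene table (columns `GENE_ID`, `FPKM`).
#' @param gene_links data.frame of gene-to-enhancer links (`GENE_ID`,
#'   `enhancer_id`, `is_super` of the linked enhancer).
#' @return A list with `buckets` (data.frame: `n_enhancers`, `composition`,
#'   `n_genes`, `median_fpkm`) and `n_unlinked`.
#' @export
expression_by_connectivity <- function(genes, gene_links) {
  linked <- unique(gene_links[, c("GENE_ID", "enhancer_id", "is_super")])
  if (nrow(linked) == 0) {
    return(list(buckets = data.frame(n_enhancers = integer(),
                                     composition = character(),
                                     n_genes = integer(),
                                     median_fpkm = numeric()),
                n_unlinked = nrow(genes)))
  }
  per_gene <- split(linked$is_super, linked$GENE_ID)
  comp <- vapply(per_gene, function(s) {
    if (all(s)) "SE-only" else if (any(s)) "mixed" else "TE-only"
  }, "")
  nlink <- vapply(per_gene, length, 0L)
  fpkm <- genes$FPKM[match(names(per_gene), genes$GENE_ID)]
  key <- paste(nlink, comp, sep = "|")
  buckets <- do.call(rbind, lapply(split(seq_along(key), key), function(idx) {
    data.frame(n_enhancers = nlink[idx[1]], composition = comp[idx[1]],
               n_genes = length(idx),
               median_fpkm = stats::median(fpkm[idx], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  buckets <- buckets[order(buckets$n_enhancers, buckets$composition), ,
                     drop = FALSE]
  rownames(buckets) <- NULL
  list(buckets = buckets,
       n_unlinked = sum(!genes$GENE_ID %in% names(per_gene)))
}
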