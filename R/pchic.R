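#' Restriction fragments, baits and interaction queries
#'
#' Fragments are a BED4-style interval set tiling each chromosome without
#' overlap; the `name` column is the fragment id. Baits are the fragments
#' that overlap at least one gene TSS, annotated with those genes.
#'
#' @param fragments Fragment interval set (column `name` = fragment id).
#' @param genes Gene table (see [read_genes()]); TSS positions 1-based.
#' @param layout Optional [genome_layout()].
#' @return `make_baits`: data.frame with `fragment_id` and `genes`
#'   (semicolon-separated gene ids).
#' @export
make_baits <- function(fragments, genes, layout = NULL) {
  tt <- gene_tss_table(genes)
  # TSS as 0-based point intervals
  tsspt <- data.frame(chrom = tt$CHR, start = tt$TSS - 1, end = tt$TSS,
                      stringsAsFactors = FALSE)
  ov <- interval_overlaps(fragments, tsspt, layout = layout)
  if (nrow(ov$pairs) == 0) {
    return(data.frame(fragment_id = character(), genes = character(),
                      stringsAsFactors = FALSE))
  }
  gl <- tapply(tt$GENE_ID[ov$pairs$b_idx], ov$pairs$a_idx,
               function(g) paste(sort(unique(g)), collapse = ";"))
  data.frame(fragment_id = fragments$name[as.integer(names(gl))],
             genes = as.character(gl), stringsAsFactors = FALSE)
}

#' Map a region to the restriction fragments it overlaps
#'
#' @param region Single-row interval set (`chrom`, `start`, `end`).
#' @param fragments Fragment interval set with `name` ids.
#' @param layout Optional [genome_layout()].
#' @return Character vector of fragment ids in genomic order.
#' @export
map_to_fragments <- function(region, fragments, layout = NULL) {
  if (!is.null(layout)) validate_intervals(region, layout)
  ov <- interval_overlaps(region, fragments, layout = layout)
  fragments$name[sort(ov$pairs$b_idx)]
}

bait_gene_list <- function(baits) {
  gl <- strsplit(baits$genes, ";", fixed = TRUE)
  names(gl) <- baits$fragment_id
  gl
}

#' Genes whose promoters a region contacts through PCHi-C
#'
#' A region is assigned the genes of every bait fragment that interacts
#' (score >= `score_min`, inclusive) with a fragment the region overlaps.
#' When an overlapped fragment is itself a bait, bait-bait interactions in
#' either stored direction contribute the partner bait's genes; interactions
#' from an overlapped bait out to a non-bait prey contribute nothing.
#'
#' @param region Single-row interval set.
#' @param fragments Fragment interval set (`name` ids).
#' @param baits Bait table from [make_baits()].
#' @param interactions Interaction table (columns `bait_id`, `oe_id`,
#'   `score`; see [read_interactions()]).
#' @param score_min Minimum interaction score (default 5, inclusive).
#' @param layout Optional [genome_layout()].
#' @return Sorted character vector of gene ids (possibly empty).
#' @export
interacting_genes <- function(region, fragments, baits, interactions,
                              score_min = 5, layout = NULL) {
  stopifnot(score_min >= 0)
  frs <- map_to_fragments(region, fragments, layout)
  genes_for_fragments(frs, baits, interactions, score_min)
}

# core lookup shared by interacting_genes and the batch annotators
genes_for_fragments <- function(frs, baits, interactions, score_min = 5) {
  if (length(frs) == 0) return(character())
  gl <- bait_gene_list(baits)
  keep <- interactions$score >= score_min
  bait_id <- interactions$bait_id[keep]
  oe_id <- interactions$oe_id[keep]
  # region on the other end: take the bait side's genes
  g1 <- unlist(gl[bait_id[oe_id %in% frs]], use.names = FALSE)
  # region on a bait: partner contributes only when itself a bait
  sel <- bait_id %in% frs & oe_id %in% names(gl)
  g2 <- unlist(gl[oe_id[sel]], use.names = FALSE)
  out <- unique(c(g1, g2))
  if (is.null(out)) character() else sort(out)
}

#' Link a set of identified regions to their interacting genes
#'
#' Vectorized [interacting_genes()] over many regions, returning one row per
#' (region, gene) pair. Used to connect enhancers or SE constituents to the
#' genes whose promoters they contact.
#'
#' @param regions Interval set with an `id` column (and optionally
#'   `is_super`).
#' @inheritParams interacting_genes
#' @return data.frame with `region_id`, `GENE_ID` and, when present in
#'   `regions`, `is_super`.
#' @export
link_regions_to_genes <- function(regions, fragments, baits, interactions,
                                  score_min = 5, layout = NULL) {
  ov <- interval_overlaps(regions, fragments, layout = layout)
  frag_of <- split(fragments$name[ov$pairs$b_idx], ov$pairs$a_idx)
  rows <- lapply(names(frag_of), function(i) {
    g <- genes_for_fragments(frag_of[[i]], baits, interactions, score_min)
    if (length(g) == 0) return(NULL)
    i <- as.integer(i)
    out <- data.frame(region_id = regions$id[i], GENE_ID = g,
                      stringsAsFactors = FALSE)
    if (!is.null(regions$is_super)) out$is_super <- regions$is_super[i]
    out
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) {
    out <- data.frame(region_id = character(), GENE_ID = character(),
                      stringsAsFactors = FALSE)
    if (!is.null(regions$is_super)) out$is_super <- logical()
    return(out)
  }
  do.call(rbind, rows)
}

#' Per-fragment feature and interaction-degree table
#'
#' For each fragment: its length, its interaction degree (number of distinct
#' partner fragments across interactions with score >= `score_min`, counting
#' both stored directions) and the number of intervals of each feature set
#' overlapping it. Fragments with no interactions or features are kept with
#' zero counts.
#'
#' @param fragments Fragment interval set (`name` ids).
#' @param interactions Interaction table.
#' @param feature_sets Named list of interval sets.
#' @param score_min Minimum score for counted interactions (default 5).
#' @param layout Optional [genome_layout()].
#' @return data.frame with `fragment_id`, `length`, `degree` and one count
#'   column per feature set.
#' @export
fragment_feature_table <- function(fragments, interactions,
                                   feature_sets = list(), score_min = 5,
                                   layout = NULL) {
  keep <- interactions$score >= score_min
  pairs <- unique(data.frame(a = interactions$bait_id[keep],
                             b = interactions$oe_id[keep],
                             stringsAsFactors = FALSE))
  partners <- c(split(pairs$b, pairs$a), split(pairs$a, pairs$b))
  deg <- vapply(fragments$name, function(f) {
    length(unique(unlist(partners[names(partners) == f], use.names = FALSE)))
  }, 0L)
  out <- data.frame(fragment_id = fragments$name,
                    length = fragments$end - fragments$start,
                    degree = as.integer(deg), stringsAsFactors = FALSE)
  for (nm in names(feature_sets)) {
    ov <- interval_overlaps(fragments, feature_sets[[nm]], layout = layout)
    cnt <- integer(nrow(fragments))
    if (nrow(ov$pairs) > 0) {
      tb <- table(ov$pairs$a_idx)
      cnt[as.integer(names(tb))] <- as.integer(tb)
    }
    out[[paste0("n_", nm)]] <- cnt
  }
  rownames(out) <- NULL
  out
}
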