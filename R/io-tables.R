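#' Tabular readers and writers for the pipeline's TSV dialects
#'
#' Variants: columns `ID, CHR, POS, TRAIT, PVAL, CONSEQUENCE, VEP_GENE`
#' (`POS` 1-based; `TRAIT` in platelet / red_cell / other; `CONSEQUENCE` in
#' exonic_or_splice / promoter_overlap_candidate / intronic_or_intergenic;
#' `VEP_GENE` empty unless exonic).
#'
#' LD: columns `SENTINEL_ID, PROXY_ID, PROXY_CHR, PROXY_POS, R2`.
#'
#' Genes: columns `GENE_ID, CHR, TSS, FPKM` with `TSS` a semicolon-separated
#' list of 1-based TSS positions.
#'
#' Interactions (ibed-style): columns `bait_chr, bait_start, bait_end,
#' bait_id, bait_genes, oe_chr, oe_start, oe_end, oe_id, score` with
#' `bait_genes` semicolon-separated.
#'
#' @param path File path.
#' @name table_io
NULL

read_tsv_checked <- function(path, required) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = NA, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("missing column(s) ", paste(miss, collapse = ", "), " in ", path)
  }
  df
}

write_tsv_plain <- function(df, path) {
  # coordinates and P-values written without scientific-notation surprises
  # for coordinates; numeric formatting left to write.table for values
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_variants <- function(path) {
  df <- read_tsv_checked(path, c("ID", "CHR", "POS", "TRAIT", "PVAL",
                                 "CONSEQUENCE", "VEP_GENE"))
  df$POS <- as.numeric(df$POS)
  df$PVAL <- as.numeric(df$PVAL)
  if (any(df$PVAL <= 0 | df$PVAL > 1, na.rm = TRUE)) {
    stop("P-values must lie in (0, 1] in ", path)
  }
  df$VEP_GENE[is.na(df$VEP_GENE)] <- ""
  df
}

#' @rdname table_io
#' @param variants Variant data.frame.
#' @export
write_variants <- function(variants, path) {
  v <- variants
  v$POS <- format_bp(v$POS)
  write_tsv_plain(v, path)
}

#' @rdname table_io
#' @export
read_ld <- function(path) {
  df <- read_tsv_checked(path, c("SENTINEL_ID", "PROXY_ID", "PROXY_CHR",
                                 "PROXY_POS", "R2"))
  df$PROXY_POS <- as.numeric(df$PROXY_POS)
  df$R2 <- as.numeric(df$R2)
  if (any(df$R2 < 0 | df$R2 > 1, na.rm = TRUE)) {
    stop("r^2 outside [0, 1] in ", path)
  }
  df
}

#' @rdname table_io
#' @param ld LD data.frame.
#' @export
write_ld <- function(ld, path) {
  x <- ld
  x$PROXY_POS <- format_bp(x$PROXY_POS)
  write_tsv_plain(x, path)
}

#' @rdname table_io
#' @export
read_genes <- function(path) {
  df <- read_tsv_checked(path, c("GENE_ID", "CHR", "TSS", "FPKM"))
  df$TSS <- as.character(df$TSS)
  df$FPKM <- as.numeric(df$FPKM)
  df
}

#' @rdname table_io
#' @param genes Gene data.frame.
#' @export
write_genes <- function(genes, path) {
  write_tsv_plain(genes, path)
}

# one row per (gene, TSS), positions numeric 1-based
gene_tss_table <- function(genes) {
  tss <- strsplit(genes$TSS, ";", fixed = TRUE)
  data.frame(GENE_ID = rep(genes$GENE_ID, lengths(tss)),
             CHR = rep(genes$CHR, lengths(tss)),
             TSS = as.numeric(unlist(tss)),
             FPKM = rep(genes$FPKM, lengths(tss)),
             stringsAsFactors = FALSE)
}

# mean TSS position per gene (used for variant-to-gene distances)
gene_mean_tss <- function(genes) {
  tt <- gene_tss_table(genes)
  agg <- stats::aggregate(TSS ~ GENE_ID + CHR, data = tt, FUN = mean)
  names(agg)[names(agg) == "TSS"] <- "MEAN_TSS"
  agg
}

#' @rdname table_io
#' @export
read_interactions <- function(path) {
  df <- read_tsv_checked(path, c("bait_chr", "bait_start", "bait_end",
                                 "bait_id", "bait_genes", "oe_chr",
                                 "oe_start", "oe_end", "oe_id", "score"))
  for (k in c("bait_start", "bait_end", "oe_start", "oe_end", "score")) {
    df[[k]] <- as.numeric(df[[k]])
  }
  if (any(df$score < 0, na.rm = TRUE)) stop("negative interaction score in ", path)
  df$bait_genes[is.na(df$bait_genes)] <- ""
  df
}

#' @rdname table_io
#' @param interactions Interaction data.frame.
#' @export
write_interactions <- function(interactions, path) {
  x <- interactions
  for (k in c("bait_start", "bait_end", "oe_start", "oe_end")) {
    x[[k]] <- format_bp(x[[k]])
  }
  write_tsv_plain(x, path)
}
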