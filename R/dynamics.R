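#' Presence patterns of reference peaks across the differentiation hierarchy
#'
#' For each open-chromatin peak of the reference terminal cell (e.g. MK
#' ATAC-seq peaks), records whether it overlaps (minimum 1 bp) a peak in each
#' progenitor population (HSC, CMP, MEP) and in the other terminal cell
#' (e.g. EB).
#'
#' @param reference_peaks Interval set of the reference cell's peaks.
#' @param progenitor_peaks Named list of interval sets; must contain `HSC`,
#'   `CMP` and `MEP`.
#' @param terminal_peaks Interval set of the other terminal cell's peaks.
#' @param layout Optional [genome_layout()].
#' @return A data.frame with one row per reference peak: `peak` (row index),
#'   logical columns `HSC`, `CMP`, `MEP`, `TERMINAL`.
#' @export
presence_patterns <- function(reference_peaks, progenitor_peaks,
                              terminal_peaks, layout = NULL) {
  need <- c("HSC", "CMP", "MEP")
  miss <- setdiff(need, names(progenitor_peaks))
  if (length(miss)) {
    stop("missing progenitor cell type(s): ", paste(miss, collapse = ", "))
  }
  hit <- function(b) interval_overlaps(reference_peaks, b, min_bp = 1,
                                       layout = layout)$hits
  data.frame(peak = seq_len(nrow(reference_peaks)),
             HSC = hit(progenitor_peaks$HSC),
             CMP = hit(progenitor_peaks$CMP),
             MEP = hit(progenitor_peaks$MEP),
             TERMINAL = hit(terminal_peaks))
}

#' Classify a presence pattern into an opening category
#'
#' Categories over (HSC, CMP, MEP, other-terminal): I = open in all five
#' cell types (1,1,1,1); II = open throughout differentiation but closed in
#' the other terminal cell (1,1,1,0); III = opened only at the final stage,
#' only in the reference cell (0,0,0,0); IV = opened at the final stage in
#' both terminal cells (0,0,0,1). All 12 remaining patterns are
#' UNCATEGORIZED and are reported, never dropped.
#'
#' @param patterns A data.frame as returned by [presence_patterns()] (columns
#'   `HSC`, `CMP`, `MEP`, `TERMINAL`).
#' @return Character vector of categories
#'   (`"I"`, `"II"`, `"III"`, `"IV"`, `"UNCATEGORIZED"`).
#' @export
categorize_opening <- function(patterns) {
  key <- paste0(as.integer(patterns$HSC), as.integer(patterns$CMP),
                as.integer(patterns$MEP), as.integer(patterns$TERMINAL))
  out <- rep("UNCATEGORIZED", length(key))
  out[key == "1111"] <- "I"
  out[key == "1110"] <- "II"
  out[key == "0000"] <- "III"
  out[key == "0001"] <- "IV"
  out
}

#' Annotate reference peaks with CTCF, enhancer and progenitor-H3K27ac labels
#'
#' CTCF binding is scored on the unpadded peak; the enhancer-state and
#' progenitor (CD34+) H3K27ac labels use peaks extended by `pad` bp to absorb
#' the positional shift between open-chromatin summits and flanking
#' acetylation signal.
#'
#' @param reference_peaks Interval set of reference peaks.
#' @param ctcf_peaks Interval set of CTCF binding sites.
#' @param enhancer_segments Interval set of enhancer-state segments.
#' @param progenitor_h3k27ac_peaks Interval set of progenitor H3K27ac peaks.
#' @param pad Pad in bp applied for the enhancer and acetylation labels
#'   (default 500).
#' @param layout A [genome_layout()] (required for padding).
#' @return A data.frame with logical columns `ctcf`, `enhancer`,
#'   `progenitor_h3k27ac`, one row per reference peak.
#' @export
annotate_labels <- function(reference_peaks, ctcf_peaks, enhancer_segments,
                            progenitor_h3k27ac_peaks, pad = 500, layout) {
  stopifnot(pad >= 0)
  # padded row-wise (not via extend_intervals) to keep row correspondence
  padded <- reference_peaks
  len <- layout$length[match(padded$chrom, layout$chrom)]
  padded$start <- pmax(0, padded$start - pad)
  padded$end <- pmin(len, padded$end + pad)
  data.frame(
    ctcf = interval_overlaps(reference_peaks, ctcf_peaks, layout = layout)$hits,
    enhancer = interval_overlaps(padded, enhancer_segments,
                                 layout = layout)$hits,
    progenitor_h3k27ac = interval_overlaps(padded, progenitor_h3k27ac_peaks,
                                           layout = layout)$hits
  )
}

#' Full opening-dynamics table for a reference peak set
#'
#' Combines [presence_patterns()], [categorize_opening()] and
#' [annotate_labels()] into the per-peak table the pipeline exports, plus a
#' per-category count summary.
#'
#' @inheritParams presence_patterns
#' @inheritParams annotate_labels
#' @return A list with `peaks` (per-peak table) and `summary` (category
#'   counts and fractions).
#' @export
opening_dynamics <- function(reference_peaks, progenitor_peaks,
                             terminal_peaks, ctcf_peaks, enhancer_segments,
                             progenitor_h3k27ac_peaks, pad = 500, layout) {
  pat <- presence_patterns(reference_peaks, progenitor_peaks, terminal_peaks,
                           layout)
  cat <- categorize_opening(pat)
  lab <- annotate_labels(reference_peaks, ctcf_peaks, enhancer_segments,
                         progenitor_h3k27ac_peaks, pad = pad, layout = layout)
  peaks <- cbind(reference_peaks[, c("chrom", "start", "end")], pat[, -1],
                 category = cat, lab)
  lev <- c("I", "II", "III", "IV", "UNCATEGORIZED")
  counts <- table(factor(cat, levels = lev))
  summary <- data.frame(category = lev, n = as.integer(counts),
                        fraction = as.numeric(counts) / max(1L, length(cat)))
  list(peaks = peaks, summary = summary)
}
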