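#' Interval sets on 0-based half-open coordinates
#'
#' An interval set is a data.frame with columns `chrom`, `start`, `end`
#' (0-based, half-open, so `start < end`) and an optional `name` column,
#' kept in canonical order: chromosome order (layout order when a layout is
#' supplied, otherwise alphabetical), then `start`, then `end`. Duplicates
#' are permitted.
#'
#' @param chrom Chromosome names.
#' @param start,end 0-based half-open coordinates.
#' @param name Optional labels (4th BED column).
#' @param layout Optional [genome_layout()]; when supplied, chromosome names
#'   and bounds are validated against it and its order becomes the sort order.
#' @return A canonical-sorted data.frame interval set.
#' @export
interval_set <- function(chrom, start, end, name = NULL, layout = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  validate_intervals(df, layout)
  sort_intervals(df, layout)
}

validate_intervals <- function(df, layout = NULL) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(!is.finite(df$start)) || any(!is.finite(df$end))) {
    stop("non-finite interval coordinates")
  }
  if (any(df$start < 0)) stop("negative interval start")
  bad <- which(df$start >= df$end)
  if (length(bad)) {
    stop("empty or inverted interval (start >= end) at row ", bad[1],
         ": ", df$chrom[bad[1]], ":", df$start[bad[1]], "-", df$end[bad[1]])
  }
  if (!is.null(layout)) {
    unk <- setdiff(unique(df$chrom), layout$chrom)
    if (length(unk)) stop("unknown chromosome(s): ", paste(unk, collapse = ", "))
    len <- layout$length[match(df$chrom, layout$chrom)]
    over <- which(df$end > len)
    if (length(over)) {
      stop("interval beyond chromosome end at row ", over[1], ": ",
           df$chrom[over[1]], ":", df$start[over[1]], "-", df$end[over[1]])
    }
  }
  invisible(df)
}

#' @rdname interval_set
#' @param x An interval set data.frame.
#' @export
sort_intervals <- function(x, layout = NULL) {
  lv <- chrom_levels(x$chrom, layout)
  o <- order(match(x$chrom, lv), x$start, x$end)
  out <- x[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# GRanges view of an interval set (1-based closed internally to IRanges;
# width is preserved: [start, end) -> [start+1, end]).
as_granges <- function(x, layout = NULL) {
  lv <- chrom_levels(x$chrom, layout)
  GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = lv),
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

#' Read a BED3/BED4 file
#'
#' Parses a tab-separated BED file (0-based half-open). A 4th column, when
#' present, is kept as `name`. Malformed lines are reported with their line
#' number.
#'
#' @param path Path to the BED file.
#' @param layout Optional [genome_layout()] used for validation and canonical
#'   chromosome order.
#' @return An interval set (see [interval_set()]).
#' @export
read_bed <- function(path, layout = NULL) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "track") &
    !startsWith(lines, "browser") & !startsWith(lines, "#")
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (length(fields) == 0) {
    return(interval_set(character(), numeric(), numeric(), layout = layout))
  }
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed BED line ", lineno[which(nf < 3)[1]], " in ", path,
         " (fewer than 3 tab-separated fields)")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop("malformed BED line ", lineno[bad[1]], " in ", path,
         " (non-numeric coordinates)")
  }
  inv <- which(start >= end)
  if (length(inv)) {
    stop("empty or inverted interval on BED line ", lineno[inv[1]],
         " in ", path)
  }
  name <- if (any(nf >= 4)) {
    vapply(fields, function(f) if (length(f) >= 4) f[[4L]] else "", "")
  } else NULL
  interval_set(chrom, start, end, name = name, layout = layout)
}

#' Write an interval set as BED3/BED4
#'
#' @param x Interval set data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- paste(x$chrom, format_bp(x$start), format_bp(x$end), sep = "\t")
  if (!is.null(x$name)) cols <- paste(cols, x$name, sep = "\t")
  writeLines(cols, path)
  invisible(path)
}

#' Extend intervals symmetrically, clamped to the chromosome
#'
#' Grows each interval by `pad` bp on both sides; coordinates are clamped to
#' `[0, chromosome length]`. Used with `pad = 500` to account for the offset
#' between open-chromatin summits and flanking H3K27ac signal.
#'
#' @param x Interval set.
#' @param pad Non-negative pad in bp.
#' @param layout [genome_layout()] supplying chromosome lengths for clamping.
#' @return The padded interval set, canonically sorted.
#' @export
extend_intervals <- function(x, pad, layout) {
  stopifnot(pad >= 0)
  if (nrow(x) == 0) return(x)
  len <- layout$length[match(x$chrom, layout$chrom)]
  if (anyNA(len)) stop("interval chromosome missing from layout")
  out <- x
  out$start <- pmax(0, x$start - pad)
  out$end <- pmin(len, x$end + pad)
  sort_intervals(out, layout)
}

#' Overlaps between two interval sets
#'
#' Marks each interval of `a` that shares at least `min_bp` bases with some
#' interval of `b`, and lists all such pairs.
#'
#' @param a,b Interval sets.
#' @param min_bp Minimum shared bases (default 1).
#' @param layout Optional [genome_layout()] for chromosome order.
#' @return A list with `hits`, a logical vector over rows of `a`, and
#'   `pairs`, a data.frame of matched row indices (`a_idx`, `b_idx`).
#' @export
interval_overlaps <- function(a, b, min_bp = 1, layout = NULL) {
  stopifnot(min_bp >= 1)
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(list(hits = logical(nrow(a)),
                pairs = data.frame(a_idx = integer(), b_idx = integer())))
  }
  lv <- chrom_levels(c(a$chrom, b$chrom), layout)
  ga <- GenomicRanges::GRanges(factor(a$chrom, lv),
                               IRanges::IRanges(a$start + 1, a$end))
  gb <- GenomicRanges::GRanges(factor(b$chrom, lv),
                               IRanges::IRanges(b$start + 1, b$end))
  ov <- GenomicRanges::findOverlaps(ga, gb, minoverlap = min_bp)
  ai <- S4Vectors::queryHits(ov)
  hits <- logical(nrow(a))
  hits[ai] <- TRUE
  list(hits = hits,
       pairs = data.frame(a_idx = ai, b_idx = S4Vectors::subjectHits(ov)))
}

#' Stitch intervals that lie within a maximum gap
#'
#' Single-linkage stitching per chromosome: consecutive sorted intervals join
#' one cluster when the gap between them (`start_next - end_prev`) is at most
#' `max_gap`; overlapping or touching intervals always join. The default
#' enhancer-stitching gap used downstream is 12,500 bp.
#'
#' @param x Interval set.
#' @param max_gap Maximum separating gap in bp (>= 0).
#' @param layout Optional [genome_layout()].
#' @return An interval set of stitched regions with a column `n_members` and
#'   an attribute `members`: a list, per stitched region, of the row indices
#'   of `x` (after canonical sorting) it absorbed.
#' @export
merge_within <- function(x, max_gap, layout = NULL) {
  stopifnot(max_gap >= 0)
  x <- sort_intervals(x, layout)
  if (nrow(x) == 0) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_members = integer())
    attr(out, "members") <- list()
    return(out)
  }
  lv <- chrom_levels(x$chrom, layout)
  gr <- GenomicRanges::GRanges(factor(x$chrom, lv),
                               IRanges::IRanges(x$start + 1, x$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1,
                               with.revmap = TRUE)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                    start = GenomicRanges::start(red) - 1,
                    end = GenomicRanges::end(red),
                    stringsAsFactors = FALSE)
  members <- lapply(S4Vectors::mcols(red)$revmap, as.integer)
  out$n_members <- lengths(members)
  o <- order(match(out$chrom, lv), out$start, out$end)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "members") <- members[o]
  out
}
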