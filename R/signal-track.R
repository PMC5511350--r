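#' Signal tracks: per-bp density over non-overlapping runs
#'
#' A signal track holds runs of constant per-bp signal density (e.g. H3K27ac
#' ChIP coverage) as a data.frame with columns `chrom`, `start`, `end`
#' (0-based half-open) and `value` (density per bp, >= 0). Runs may not
#' overlap within a chromosome; uncovered bases have value 0. A library-size
#' `scale` factor is carried and applied at summation time so that treatment
#' and input tracks are comparable.
#'
#' @param chrom,start,end,value Run coordinates and densities.
#' @param scale Multiplicative scale factor (e.g. per-million normalization).
#' @param layout Optional [genome_layout()] for validation.
#' @return A `signal_track` data.frame with attribute `scale`.
#' @export
signal_track <- function(chrom, start, end, value, scale = 1, layout = NULL) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), value = as.numeric(value),
                   stringsAsFactors = FALSE)
  validate_intervals(df, layout)
  if (any(!is.finite(df$value)) || any(df$value < 0)) {
    stop("signal values must be finite and >= 0")
  }
  df <- sort_intervals(df, layout)
  if (nrow(df) > 1) {
    same <- df$chrom[-1] == df$chrom[-nrow(df)]
    if (any(same & df$start[-1] < df$end[-nrow(df)])) {
      stop("overlapping runs within a chromosome")
    }
  }
  stopifnot(is.finite(scale), scale > 0)
  attr(df, "scale") <- scale
  class(df) <- c("signal_track", "data.frame")
  df
}

#' Read a bedGraph file as a signal track
#'
#' @param path Path to a 4-column bedGraph (chrom, start, end, value).
#' @param scale Scale factor to attach (see [signal_track()]).
#' @param layout Optional [genome_layout()].
#' @return A [signal_track()].
#' @export
read_bedgraph <- function(path, scale = 1, layout = NULL) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "track") & !startsWith(lines, "#")
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (length(fields) == 0) {
    return(signal_track(character(), numeric(), numeric(), numeric(),
                        scale = scale, layout = layout))
  }
  if (any(lengths(fields) < 4)) {
    stop("malformed bedGraph line ",
         lineno[which(lengths(fields) < 4)[1]], " in ", path)
  }
  num <- function(k) suppressWarnings(as.numeric(vapply(fields, `[[`, "", k)))
  start <- num(2L); end <- num(3L); value <- num(4L)
  bad <- which(is.na(start) | is.na(end) | is.na(value))
  if (length(bad)) {
    stop("malformed bedGraph line ", lineno[bad[1]], " in ", path)
  }
  signal_track(vapply(fields, `[[`, "", 1L), start, end, value,
               scale = scale, layout = layout)
}

#' Write a signal track as bedGraph
#'
#' @param track A [signal_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  writeLines(paste(track$chrom, format_bp(track$start), format_bp(track$end),
                   format(track$value, scientific = FALSE, trim = TRUE),
                   sep = "\t"),
             path)
  invisible(path)
}

#' Sum signal over an interval, with exclusions
#'
#' Returns the scaled sum of density x covered-bp over `interval`, not
#' counting bases that fall inside `exclude` (e.g. promoter regions and
#' blacklisted regions removed before enhancer ranking).
#'
#' @param track A [signal_track()].
#' @param interval A single-row interval set (or list with `chrom`, `start`,
#'   `end`).
#' @param exclude Optional interval set of bases to discard.
#' @return Scaled signal sum (numeric scalar).
#' @export
signal_sum <- function(track, interval, exclude = NULL) {
  chrom <- interval$chrom[1]
  lo <- interval$start[1]
  hi <- interval$end[1]
  runs <- track[track$chrom == chrom & track$end > lo & track$start < hi, ,
                drop = FALSE]
  if (nrow(runs) == 0) return(0)
  rs <- pmax(runs$start, lo)
  re <- pmin(runs$end, hi)
  eff <- re - rs
  if (!is.null(exclude) && nrow(exclude) > 0) {
    ex <- exclude[exclude$chrom == chrom & exclude$end > lo &
                    exclude$start < hi, , drop = FALSE]
    if (nrow(ex) > 0) {
      ir <- IRanges::reduce(IRanges::IRanges(pmax(ex$start, lo) + 1,
                                             pmin(ex$end, hi)))
      runsr <- IRanges::IRanges(rs + 1, re)
      ov <- IRanges::findOverlaps(runsr, ir)
      if (length(ov) > 0) {
        w <- IRanges::width(IRanges::pintersect(
          runsr[S4Vectors::queryHits(ov)], ir[S4Vectors::subjectHits(ov)]))
        cut <- tapply(w, S4Vectors::queryHits(ov), sum)
        eff[as.integer(names(cut))] <- eff[as.integer(names(cut))] - cut
      }
    }
  }
  sum(runs$value * eff) * attr(track, "scale")
}
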