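#' Genome layout: ordered chromosomes and their lengths
#'
#' The layout fixes the chromosome order used everywhere downstream: canonical
#' interval sorting, and the concatenation (circularization) order of the
#' circular permutation test, where the first chromosome is taken to follow
#' the last one.
#'
#' @param chrom Character vector of unique chromosome names, in karyotype
#'   order.
#' @param length Numeric vector of chromosome lengths in bp (> 0).
#' @return A `genome_layout`: a data.frame with columns `chrom` and `length`,
#'   row order = karyotype order.
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) {
    stop("duplicate chromosome names in layout: ",
         paste(unique(chrom[duplicated(chrom)]), collapse = ", "))
  }
  if (length(chrom) != base::length(length)) {
    stop("chrom and length differ in length")
  }
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be finite and > 0")
  }
  out <- data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' Read a two-column chromosome-sizes file
#'
#' @param path Path to a TSV with columns chromosome name and length, no
#'   header. File order defines the karyotype order.
#' @return A [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (base::length(f) < 2 || is.na(suppressWarnings(as.numeric(f[2])))) {
      stop("malformed chromosome-sizes line ", i, " in ", path)
    }
  }
  genome_layout(vapply(fields, `[[`, "", 1L),
                vapply(fields, function(f) as.numeric(f[2]), 0))
}

#' Write a chromosome-sizes file
#'
#' @param layout A [genome_layout()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(layout, path) {
  writeLines(paste(layout$chrom, format_bp(layout$length), sep = "\t"), path)
  invisible(path)
}

# bp coordinates as plain integers (never scientific notation)
format_bp <- function(x) {
  format(x, scientific = FALSE, trim = TRUE)
}

chrom_levels <- function(x, layout = NULL) {
  if (!is.null(layout)) layout$chrom else sort(unique(as.character(x)))
}
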