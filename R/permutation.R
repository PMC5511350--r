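#' Order variants along the circularized genome
#'
#' Sorts variants by karyotype chromosome order, then position, breaking
#' position ties by variant id. Index i's successor is i + 1, and the last
#' variant's successor is the first: the first chromosome is taken to follow
#' the last one, so shifted P-values wrap around the genome.
#'
#' @param variants Variant table (columns `ID`, `CHR`, `POS`, ...).
#' @param layout A [genome_layout()] fixing the chromosome order.
#' @return The variant table in circular order.
#' @export
circular_layout <- function(variants, layout) {
  o <- order(match(variants$CHR, layout$chrom), variants$POS, variants$ID)
  out <- variants[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rotate a P-value vector along the circular layout
#'
#' Position `i` receives the P-value originally at index `(i - offset) mod
#' n`; variant positions, traits and region memberships stay fixed, so
#' local correlation between nearby P-values is preserved.
#'
#' @param pvalues Numeric vector in circular order.
#' @param offset Integer in `[0, n)`.
#' @return The rotated vector.
#' @export
circular_shift <- function(pvalues, offset) {
  n <- length(pvalues)
  if (offset < 0 || offset >= n) stop("offset out of range [0, n)")
  pvalues[((seq_len(n) - 1 - offset) %% n) + 1]
}

# all-offset circular cross-correlation C[o+1] = sum_j s_j w[(j+o) mod n],
# exact for 0/1 indicators after rounding
crosscor_all <- function(s, w) {
  n <- length(s)
  round(Re(stats::fft(Conj(stats::fft(s)) * stats::fft(w),
                      inverse = TRUE)) / n)
}

# per-offset statistics for offsets 0..n-1
perm_stats_all <- function(pvalues, membership, fg, bg, mode, sig_threshold) {
  n <- length(pvalues)
  sig <- as.numeric(pvalues < sig_threshold)
  if (sum(sig) == 0) {
    base <- if (mode == "count") 0 else 1
    return(rep(base, n))
  }
  a <- crosscor_all(sig, as.numeric(fg & membership))   # sig fg in region
  if (mode == "count") return(a)
  A <- crosscor_all(sig, as.numeric(fg))                # sig fg total
  if (mode == "hypergeom_tail") {
    m <- sum(fg & membership)
    return(stats::phyper(a - 1, m, sum(fg) - m, A, lower.tail = FALSE))
  }
  cc <- crosscor_all(sig, as.numeric(bg & membership))  # sig bg in region
  B <- crosscor_all(sig, as.numeric(bg))                # sig bg total
  b <- A - a
  d <- B - cc
  p <- stats::phyper(a - 1, a + b, cc + d, a + cc, lower.tail = FALSE)
  p[a + b + cc + d == 0] <- 1
  p
}

#' Per-dataset enrichment statistic
#'
#' Three statistics over the (possibly rotated) P-value vector:
#' `count` — the number of foreground-trait variants significant below
#' `sig_threshold` inside the region set; `hypergeom_tail` — the upper-tail
#' probability of seeing at least that count, for a hypergeometric draw of
#' the significant foreground variants from all foreground variants;
#' `trait_contrast` — a one-sided exact P contrasting significant
#' foreground- versus background-trait variants inside versus outside the
#' region set.
#'
#' @param pvalues Numeric vector in circular order.
#' @param membership Logical: variant lies in the region set.
#' @param fg,bg Logical: foreground-/background-trait variant. Variants in
#'   neither group (e.g. pleiotropic) still occupy rotation slots but are
#'   not counted.
#' @param mode One of `"count"`, `"hypergeom_tail"`, `"trait_contrast"`.
#' @param sig_threshold Significance threshold in (0, 1) (default 5e-8).
#' @return Numeric scalar.
#' @export
dataset_statistic <- function(pvalues, membership, fg, bg = !fg,
                              mode = c("trait_contrast", "count",
                                       "hypergeom_tail"),
                              sig_threshold = 5e-8) {
  mode <- match.arg(mode)
  stopifnot(sig_threshold > 0, sig_threshold < 1)
  perm_stats_all(pvalues, membership, fg, bg, mode, sig_threshold)[1]
}

#' Circular genomic permutation enrichment test
#'
#' Rotates the genome-ordered P-value vector `n_shifts` times (offsets drawn
#' uniformly with replacement from 1..n-1, or every non-zero rotation once
#' in exhaustive mode), recomputes the per-dataset statistic after each
#' rotation, and reports the rank of the observed dataset among all
#' `n_shifts + 1` datasets as an empirical P-value. Larger counts and
#' smaller tail P-values count as more extreme; ties count as at least as
#' extreme; the add-one rule makes the empirical P never zero, and with
#' 999,999 shifts it is the observed rank divided by 1,000,000.
#'
#' @param variants Variant table (`ID`, `CHR`, `POS`, `TRAIT`, `PVAL`).
#' @param regions Interval set defining the foreground region set.
#' @param layout A [genome_layout()] (circularization order).
#' @param foreground,background Trait labels contrasted (defaults
#'   `"platelet"` vs `"red_cell"`).
#' @param mode Statistic, see [dataset_statistic()].
#' @param sig_threshold Significance threshold (default 5e-8).
#' @param n_shifts Number of random rotations (default 999999).
#' @param seed Optional integer seed for offset sampling.
#' @param exhaustive When TRUE, uses every offset 1..n-1 exactly once.
#' @return A `perm_result` list: `observed`, `shifted` (statistics),
#'   `rank`, `p_empirical`, `mode`, `n_shifts`, `n_variants`.
#' @export
circular_permutation_test <- function(variants, regions, layout,
                                      foreground = "platelet",
                                      background = "red_cell",
                                      mode = c("trait_contrast", "count",
                                               "hypergeom_tail"),
                                      sig_threshold = 5e-8,
                                      n_shifts = 999999, seed = NULL,
                                      exhaustive = FALSE) {
  mode <- match.arg(mode)
  stopifnot(sig_threshold > 0, sig_threshold < 1)
  v <- circular_layout(variants, layout)
  n <- nrow(v)
  if (n < 3) stop("need at least 3 variants for a non-degenerate rotation")
  pts <- data.frame(chrom = v$CHR, start = v$POS - 1, end = v$POS,
                    stringsAsFactors = FALSE)
  membership <- interval_overlaps(pts, regions, layout = layout)$hits
  fg <- v$TRAIT == foreground
  bg <- v$TRAIT == background
  stats_all <- perm_stats_all(v$PVAL, membership, fg, bg, mode,
                              sig_threshold)
  if (exhaustive) {
    offsets <- seq_len(n - 1)
  } else {
    stopifnot(n_shifts >= 1)
    if (!is.null(seed)) set.seed(seed)
    offsets <- sample.int(n - 1, n_shifts, replace = TRUE)
  }
  observed <- stats_all[1]
  shifted <- stats_all[offsets + 1]
  extreme <- if (mode == "count") shifted >= observed else shifted <= observed
  rank <- 1 + sum(extreme)
  structure(list(observed = observed, shifted = shifted, rank = rank,
                 p_empirical = rank / (length(offsets) + 1), mode = mode,
                 n_shifts = length(offsets), n_variants = n),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat("Circular permutation test (", x$mode, ")\n", sep = "")
  cat("  variants:", x$n_variants, " shifts:", x$n_shifts, "\n")
  cat("  observed statistic:", format(x$observed), "\n")
  cat("  rank:", x$rank, " empirical P:", format(x$p_empirical), "\n")
  invisible(x)
}
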