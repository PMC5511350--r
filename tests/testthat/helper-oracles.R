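# Independent brute-force oracles. These deliberately avoid the package's
# interval/permutation machinery: plain loops over base-R structures only.

tiny_layout <- function(n = 2, len = 100000) {
  genome_layout(paste0("chr", seq_len(n)), rep(len, n))
}

random_intervals <- function(n, layout, max_len = 500) {
  chrom <- sample(layout$chrom, n, replace = TRUE)
  len <- layout$length[match(chrom, layout$chrom)]
  start <- floor(runif(n, 0, len - max_len - 1))
  width <- sample.int(max_len, n, replace = TRUE)
  interval_set(chrom, start, start + width, layout = layout)
}

# quadratic all-pairs overlap check
bf_overlap_pairs <- function(a, b, min_bp = 1) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      shared <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (shared >= min_bp) out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (length(out) == 0) {
    return(data.frame(a_idx = integer(), b_idx = integer()))
  }
  m <- do.call(rbind, out)
  o <- order(m[, 1], m[, 2])
  data.frame(a_idx = m[o, 1], b_idx = m[o, 2])
}

# transitive-closure clustering: i ~ j if same chrom and gap <= max_gap,
# then take the closure
bf_merge <- function(x, max_gap) {
  n <- nrow(x)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || x$chrom[i] != x$chrom[j]) next
      gap <- max(x$start[i], x$start[j]) - min(x$end[i], x$end[j])
      if (gap <= max_gap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  out <- do.call(rbind, lapply(split(seq_len(n), root), function(idx) {
    data.frame(chrom = x$chrom[idx[1]], start = min(x$start[idx]),
               end = max(x$end[idx]), n_members = length(idx),
               stringsAsFactors = FALSE)
  }))
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

# per-base signal summation
bf_signal_sum <- function(track, interval, exclude = NULL) {
  total <- 0
  for (p in seq(interval$start[1], interval$end[1] - 1)) {
    if (!is.null(exclude) && nrow(exclude) > 0) {
      skip <- any(exclude$chrom == interval$chrom[1] &
                    exclude$start <= p & p < exclude$end)
      if (skip) next
    }
    sel <- track$chrom == interval$chrom[1] & track$start <= p & p < track$end
    if (any(sel)) total <- total + track$value[sel][1]
  }
  total * attr(track, "scale")
}

# brute-force tangent scan on the scaled ascending curve
bf_tangent_cutoff <- function(scores) {
  n <- length(scores)
  y <- sort(scores)
  x <- (seq_len(n) - 1) / (n - 1)
  rng <- y[n] - y[1]
  ys <- if (rng > 0) (y - y[1]) / rng else rep(0, n)
  best <- 1
  for (i in seq_len(n)) if (x[i] - ys[i] > x[best] - ys[best]) best <- i
  list(index = best, score = y[best])
}

# naive statistic on an explicitly rotated P-value vector
bf_statistic <- function(pvals, mem, fg, bg, mode, thr) {
  sig <- pvals < thr
  a <- sum(sig & fg & mem)
  if (mode == "count") return(a)
  if (mode == "hypergeom_tail") {
    m <- sum(fg & mem)
    return(phyper(a - 1, m, sum(fg) - m, sum(sig & fg), lower.tail = FALSE))
  }
  b <- sum(sig & fg & !mem)
  cc <- sum(sig & bg & mem)
  d <- sum(sig & bg & !mem)
  if (a + b + cc + d == 0) return(1)
  phyper(a - 1, a + b, cc + d, a + cc, lower.tail = FALSE)
}

# materialize every rotation independently and rank the observed
bf_exhaustive_test <- function(pvals, mem, fg, bg, mode, thr) {
  n <- length(pvals)
  obs <- bf_statistic(pvals, mem, fg, bg, mode, thr)
  shifted <- vapply(seq_len(n - 1), function(off) {
    rot <- pvals[((seq_len(n) - 1 - off) %% n) + 1]
    bf_statistic(rot, mem, fg, bg, mode, thr)
  }, 0)
  extreme <- if (mode == "count") shifted >= obs else shifted <= obs
  rank <- 1 + sum(extreme)
  list(observed = obs, shifted = shifted, rank = rank,
       p_empirical = rank / n)
}

# two-sided exact P by full enumeration of the hypergeometric support
bf_fisher_two_sided <- function(a, b, cc, d) {
  m <- a + b; n2 <- cc + d; k <- a + cc
  if (m + n2 == 0 || k == 0 || k == m + n2) return(1)
  support <- max(0, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
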