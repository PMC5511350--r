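#' Configuration of the synthetic study generator
#'
#' Defines the shape of a desk-scale synthetic study: genome, restriction
#' fragment grid, genes, enhancer landscape with planted super-enhancer
#' clusters, open-chromatin opening patterns, promoter-anchored
#' interactions, and GWAS-like variant sets with block LD and a planted
#' enrichment of significant P-values inside a designated region set
#' (foreground-trait variants inside MK-specific SE constituents have their
#' odds of significance multiplied by `theta`).
#'
#' @param seed Integer seed; one seed governs every draw.
#' @param n_chromosomes,chrom_length Genome shape (default 4 x 4 Mb).
#' @param frag_mean,frag_min,frag_max Restriction fragment length
#'   distribution in bp (exponential around ~4 kb, truncated).
#' @param n_genes Number of genes.
#' @param n_dispersed_enhancers Isolated (typical) enhancers per cell type.
#' @param n_se_clusters Planted SE clusters per cell type.
#' @param frac_shared_se Fraction of clusters shared between MK and EB.
#' @param constituents_range Min/max constituents per cluster.
#' @param n_extra_peaks Open-chromatin peaks not tied to enhancers.
#' @param n_decoy_enhancers Enhancers planted within 1 kb of a promoter
#'   segment (removed by the promoter filter).
#' @param category_fracs Named fractions of reference peaks per opening
#'   category (`I`, `II`, `III`, `IV`); the remainder is uncategorized.
#' @param n_platelet,n_redcell Sentinel variants per trait.
#' @param frac_exonic,frac_promoter,frac_in_enhancer Variant placement
#'   fractions (exonic near a TSS, inside a promoter segment, inside MK
#'   enhancer bases); the rest is uniform over the genome.
#' @param theta Planted enrichment odds multiplier (>= 0); 1 = no
#'   enrichment.
#' @param sig_rate Baseline probability that a variant is significant.
#' @param sig_magnitude Significant variants draw P ~ U(0, sig_magnitude).
#' @param proxies_mean Mean LD proxies per sentinel (Poisson).
#' @param ld_window Proxy positions fall within this many bp of their
#'   sentinel.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_chromosomes = 4, chrom_length = 4e6,
                       frag_mean = 4000, frag_min = 500, frag_max = 10000,
                       n_genes = 240, n_dispersed_enhancers = 200,
                       n_se_clusters = 12, frac_shared_se = 1 / 3,
                       constituents_range = c(4, 10), n_extra_peaks = 150,
                       n_decoy_enhancers = 20,
                       category_fracs = c(I = 0.38, II = 0.15, III = 0.20,
                                          IV = 0.147),
                       n_platelet = 400, n_redcell = 400,
                       frac_exonic = 0.08, frac_promoter = 0.05,
                       frac_in_enhancer = 0.30, theta = 5,
                       sig_rate = 0.15, sig_magnitude = 1e-9,
                       proxies_mean = 3, ld_window = 25000) {
  cfg <- as.list(environment())
  stopifnot(theta >= 0, sum(category_fracs) <= 1,
            all(category_fracs >= 0), sig_rate > 0, sig_rate < 1,
            frac_exonic + frac_promoter + frac_in_enhancer <= 1,
            n_platelet >= 0, n_redcell >= 0, frag_max < 12500)
  class(cfg) <- "sim_config"
  cfg
}

# presence flags (HSC, CMP, MEP, EB) implied by an opening category
category_pattern <- function(category) {
  switch(category,
         I = c(1, 1, 1, 1), II = c(1, 1, 1, 0),
         III = c(0, 0, 0, 0), IV = c(0, 0, 0, 1),
         stop("no fixed pattern for category ", category))
}

# the 12 presence patterns that map to no named category
uncategorized_patterns <- function() {
  pats <- expand.grid(HSC = 0:1, CMP = 0:1, MEP = 0:1, EB = 0:1)
  named <- c("1111", "1110", "0000", "0001")
  key <- apply(pats, 1, paste, collapse = "")
  as.matrix(pats[!key %in% named, , drop = FALSE])
}

#' Generate a synthetic study
#'
#' Lays out non-overlapping features (SE clusters, dispersed enhancers,
#' genes with promoter segments, decoy promoter-proximal enhancers, extra
#' open-chromatin peaks) with at least ~12.6 kb between features so planted
#' clusters, and only they, survive enhancer stitching; builds H3K27ac
#' treatment and input tracks with cluster constituents at >= 10x the
#' signal density of dispersed enhancers; draws a fragment grid and
#' promoter-anchored interactions whose cluster fragments link only to each
#' cluster's designated target genes; and allocates variant significance
#' with odds multiplied by `theta` for platelet variants inside the
#' designated MK-specific SE constituents.
#'
#' @param config A [sim_config()].
#' @return A `synthetic_dataset` list: `layout`, `peaks` (MK, EB, HSC, CMP,
#'   MEP), `ctcf`, `cd34_h3k27ac`, `enhancers` (MK, EB), `promoters`,
#'   `signal` (per cell type treatment/input), `fragments`, `genes`,
#'   `interactions`, `variants`, `ld`, `truth`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  L <- cfg$chrom_length
  layout <- genome_layout(paste0("chr", seq_len(cfg$n_chromosomes)),
                          rep(L, cfg$n_chromosomes))

  ## ---- feature objects and their genomic spans ----
  n_shared <- round(cfg$n_se_clusters * cfg$frac_shared_se)
  n_spec <- cfg$n_se_clusters - n_shared
  cluster_cells <- c(rep("shared", n_shared), rep("MK", n_spec),
                     rep("EB", n_spec))
  k_lo <- cfg$constituents_range[1]
  k_hi <- cfg$constituents_range[2]
  clusters <- lapply(seq_along(cluster_cells), function(i) {
    k <- sample(k_lo:k_hi, 1)
    w <- round(stats::runif(k, 1000, 2000))
    g <- if (k > 1) round(stats::runif(k - 1, 1500, 4000)) else numeric()
    off <- cumsum(c(0, w[-k] + g))
    list(cell = cluster_cells[i], k = k, rel_start = off,
         rel_end = off + w, span = off[k] + w[k])
  })
  objects <- c(
    lapply(seq_along(clusters), function(i)
      list(type = "cluster", idx = i, width = clusters[[i]]$span)),
    lapply(seq_len(cfg$n_dispersed_enhancers), function(i)
      list(type = "disp_MK", idx = i,
           width = round(stats::runif(1, 800, 1200)))),
    lapply(seq_len(cfg$n_dispersed_enhancers), function(i)
      list(type = "disp_EB", idx = i,
           width = round(stats::runif(1, 800, 1200)))),
    lapply(seq_len(cfg$n_genes), function(i)
      list(type = "gene", idx = i, width = 3000)),
    lapply(seq_len(cfg$n_decoy_enhancers), function(i)
      list(type = "decoy", idx = i,
           width = 2200 + round(stats::runif(1, 150, 800)))),
    lapply(seq_len(cfg$n_extra_peaks), function(i)
      list(type = "peak", idx = i, width = 600))
  )
  objects <- objects[sample.int(length(objects))]

  cursor <- rep(10000, cfg$n_chromosomes)
  placed <- vector("list", length(objects))
  for (i in seq_along(objects)) {
    ch <- which.min(cursor)
    gap <- round(stats::runif(1, 12600, 16000))
    pos <- cursor[ch] + gap
    if (pos + objects[[i]]$width > L - 10000) {
      stop("infeasible config: features do not fit on the genome")
    }
    placed[[i]] <- c(objects[[i]], chrom = layout$chrom[ch], start = pos)
    cursor[ch] <- pos + objects[[i]]$width
  }

  ## ---- enhancers, promoters, clusters, genes ----
  get_placed <- function(type) Filter(function(o) o$type == type, placed)
  emptyiv <- function() data.frame(chrom = character(), start = numeric(),
                                   end = numeric(), stringsAsFactors = FALSE)
  cluster_rows <- list()
  for (o in get_placed("cluster")) {
    cl <- clusters[[o$idx]]
    cluster_rows[[length(cluster_rows) + 1]] <- data.frame(
      cluster_id = sprintf("CL%02d", o$idx), cell = cl$cell,
      chrom = o$chrom, start = o$start + cl$rel_start,
      end = o$start + cl$rel_end, stringsAsFactors = FALSE)
  }
  cluster_tab <- do.call(rbind, cluster_rows)

  disp <- list()
  for (cell in c("MK", "EB")) {
    rows <- get_placed(paste0("disp_", cell))
    disp[[cell]] <- data.frame(
      chrom = vapply(rows, `[[`, "", "chrom"),
      start = vapply(rows, `[[`, 0, "start"),
      end = vapply(rows, function(o) o$start + o$width, 0),
      stringsAsFactors = FALSE)
  }

  gene_rows <- get_placed("gene")
  n_tss2 <- stats::runif(length(gene_rows)) < 0.3
  has_prom <- stats::runif(length(gene_rows)) < 0.85
  gene_chrom <- vapply(gene_rows, `[[`, "", "chrom")
  gene_pos <- vapply(gene_rows, `[[`, 0, "start")
  tss1 <- gene_pos + 701                       # 1-based
  fpkm <- signif(stats::rlnorm(length(gene_rows), meanlog = 1.5,
                               sdlog = 1.5), 3)
  genes <- data.frame(
    GENE_ID = sprintf("G%04d", seq_along(gene_rows)),
    CHR = gene_chrom,
    TSS = ifelse(n_tss2, paste(tss1, tss1 + 2000, sep = ";"),
                 as.character(tss1)),
    FPKM = fpkm, stringsAsFactors = FALSE)
  promoters_gene <- data.frame(chrom = gene_chrom[has_prom],
                               start = gene_pos[has_prom],
                               end = gene_pos[has_prom] + 1400,
                               stringsAsFactors = FALSE)

  decoy_rows <- get_placed("decoy")
  decoy_enh <- emptyiv(); decoy_prom <- emptyiv()
  if (length(decoy_rows)) {
    dpos <- vapply(decoy_rows, `[[`, 0, "start")
    dch <- vapply(decoy_rows, `[[`, "", "chrom")
    dwidth <- vapply(decoy_rows, `[[`, 0, "width")
    dgap <- dwidth - 2200                      # the planted < 1 kb gap
    decoy_enh <- data.frame(chrom = dch, start = dpos, end = dpos + 800,
                            stringsAsFactors = FALSE)
    decoy_prom <- data.frame(chrom = dch, start = dpos + 800 + dgap,
                             end = dpos + 2200 + dgap,
                             stringsAsFactors = FALSE)
  }
  promoters <- sort_intervals(rbind(promoters_gene, decoy_prom), layout)

  enh_tab <- function(cell) {
    cl <- cluster_tab[cluster_tab$cell %in% c(cell, "shared"), , drop = FALSE]
    out <- rbind(
      data.frame(chrom = cl$chrom, start = cl$start, end = cl$end,
                 role = "constituent", stringsAsFactors = FALSE),
      data.frame(chrom = disp[[cell]]$chrom, start = disp[[cell]]$start,
                 end = disp[[cell]]$end, role = "dispersed",
                 stringsAsFactors = FALSE),
      if (cell == "MK" && nrow(decoy_enh))
        data.frame(chrom = decoy_enh$chrom, start = decoy_enh$start,
                   end = decoy_enh$end, role = "decoy",
                   stringsAsFactors = FALSE))
    out <- sort_intervals(out, layout)
    out$name <- sprintf("%s_E%04d", cell, seq_len(nrow(out)))
    out
  }
  enhancers <- list(MK = enh_tab("MK"), EB = enh_tab("EB"))

  ## ---- H3K27ac treatment and input tracks ----
  make_signal <- function(cell) {
    e <- enhancers[[cell]]
    value <- numeric(nrow(e))
    value[e$role == "constituent"] <- stats::runif(
      sum(e$role == "constituent"), 15, 25)
    value[e$role == "dispersed"] <- stats::runif(
      sum(e$role == "dispersed"), 1.0, 1.4)
    value[e$role == "decoy"] <- stats::runif(sum(e$role == "decoy"), 5, 10)
    runs <- rbind(
      data.frame(chrom = e$chrom, start = e$start, end = e$end,
                 value = round(value, 4), stringsAsFactors = FALSE),
      data.frame(chrom = promoters$chrom, start = promoters$start,
                 end = promoters$end,
                 value = round(stats::runif(nrow(promoters), 3, 6), 4),
                 stringsAsFactors = FALSE))
    treat <- signal_track(runs$chrom, runs$start, runs$end, runs$value,
                          layout = layout)
    input <- signal_track(runs$chrom, runs$start, runs$end,
                          round(stats::runif(nrow(runs), 0.05, 0.15), 4),
                          layout = layout)
    list(treatment = treat, input = input)
  }
  signal <- list(MK = make_signal("MK"), EB = make_signal("EB"))

  ## ---- open chromatin peaks with planted opening patterns ----
  upats <- uncategorized_patterns()
  draw_patterns <- function(n) {
    fr <- cfg$category_fracs
    cats <- sample(c(names(fr), "UNCATEGORIZED"), n, replace = TRUE,
                   prob = c(fr, 1 - sum(fr)))
    flags <- matrix(0L, n, 4,
                    dimnames = list(NULL, c("HSC", "CMP", "MEP", "EB")))
    for (i in seq_len(n)) {
      flags[i, ] <- if (cats[i] == "UNCATEGORIZED") {
        upats[sample.int(nrow(upats), 1), ]
      } else category_pattern(cats[i])
    }
    list(category = cats, flags = flags)
  }

  mk_src <- enhancers$MK[enhancers$MK$role != "decoy", , drop = FALSE]
  extra_rows <- get_placed("peak")
  extra <- data.frame(chrom = vapply(extra_rows, `[[`, "", "chrom"),
                      start = vapply(extra_rows, `[[`, 0, "start"),
                      end = vapply(extra_rows,
                                   function(o) o$start + o$width, 0),
                      stringsAsFactors = FALSE)
  mk_peaks <- rbind(mk_src[, c("chrom", "start", "end")], extra)
  mk_peaks$start <- pmax(0, mk_peaks$start -
                           round(stats::runif(nrow(mk_peaks), 0, 150)))
  mk_peaks$end <- pmin(L, mk_peaks$end +
                         round(stats::runif(nrow(mk_peaks), 0, 150)))
  mk_peaks <- sort_intervals(mk_peaks, layout)
  pat_mk <- draw_patterns(nrow(mk_peaks))

  # EB-specific enhancers carry their own (jittered) peaks and patterns
  eb_own <- enhancers$EB[enhancers$EB$role == "dispersed" |
                           !paste(enhancers$EB$chrom, enhancers$EB$start) %in%
                           paste(enhancers$MK$chrom, enhancers$MK$start), ,
                         drop = FALSE]
  eb_own <- eb_own[, c("chrom", "start", "end")]
  eb_own$start <- pmax(0, eb_own$start -
                         round(stats::runif(nrow(eb_own), 0, 150)))
  eb_own$end <- pmin(L, eb_own$end +
                       round(stats::runif(nrow(eb_own), 0, 150)))
  pat_eb <- draw_patterns(nrow(eb_own))

  jitter_copy <- function(iv, keep) {
    iv <- iv[keep, , drop = FALSE]
    if (nrow(iv) == 0) return(emptyiv())
    d1 <- round(stats::runif(nrow(iv), -100, 100))
    d2 <- round(stats::runif(nrow(iv), -100, 100))
    data.frame(chrom = iv$chrom, start = pmax(0, iv$start + d1),
               end = pmin(L, iv$end + d2), stringsAsFactors = FALSE)
  }
  prog_set <- function(col) {
    sort_intervals(rbind(jitter_copy(mk_peaks, pat_mk$flags[, col] == 1),
                         jitter_copy(eb_own, pat_eb$flags[, col] == 1)),
                   layout)
  }
  peaks <- list(
    MK = mk_peaks,
    EB = sort_intervals(rbind(jitter_copy(mk_peaks,
                                          pat_mk$flags[, "EB"] == 1),
                              eb_own), layout),
    HSC = prog_set("HSC"), CMP = prog_set("CMP"), MEP = prog_set("MEP"))

  ctcf_pick <- stats::runif(nrow(mk_peaks)) < 0.35
  mid <- round((mk_peaks$start + mk_peaks$end) / 2)
  ctcf <- data.frame(chrom = mk_peaks$chrom[ctcf_pick],
                     start = pmax(mk_peaks$start[ctcf_pick],
                                  mid[ctcf_pick] - 200),
                     end = pmin(mk_peaks$end[ctcf_pick],
                                mid[ctcf_pick] + 200),
                     stringsAsFactors = FALSE)
  ctcf <- sort_intervals(ctcf, layout)
  cd34_pick <- pat_mk$flags[, "HSC"] == 1 & stats::runif(nrow(mk_peaks)) < 0.66
  cd34 <- sort_intervals(jitter_copy(mk_peaks, cd34_pick), layout)

  ## ---- fragment grid ----
  frag_list <- lapply(seq_len(cfg$n_chromosomes), function(ch) {
    need <- ceiling(2 * L / cfg$frag_mean) + 20
    lens <- pmin(cfg$frag_max,
                 pmax(cfg$frag_min, round(stats::rexp(need, 1 / cfg$frag_mean))))
    ends <- cumsum(lens)
    if (ends[length(ends)] < L) stop("fragment draw too short; raise need")
    ends <- c(ends[ends < L], L)
    data.frame(chrom = layout$chrom[ch], start = c(0, ends[-length(ends)]),
               end = ends, stringsAsFactors = FALSE)
  })
  fragments <- do.call(rbind, frag_list)
  fragments <- sort_intervals(fragments, layout)
  fragments$name <- sprintf("F%05d", seq_len(nrow(fragments)))

  frag_at <- function(chrom, pos0) {
    # fragment containing 0-based position pos0 (vectorized per chromosome)
    out <- character(length(chrom))
    for (ch in unique(chrom)) {
      sel <- fragments$chrom == ch
      ii <- chrom == ch
      out[ii] <- fragments$name[sel][findInterval(pos0[ii],
                                                  fragments$start[sel])]
    }
    out
  }
  baits <- make_baits(fragments, genes, layout)
  gene_tss1 <- as.numeric(vapply(strsplit(genes$TSS, ";", fixed = TRUE),
                                 `[[`, "", 1L))
  gene_bait_frag <- frag_at(genes$CHR, gene_tss1 - 1)
  names(gene_bait_frag) <- genes$GENE_ID
  bait_frag_of_gene <- function(gid) unname(gene_bait_frag[gid])

  ## ---- interactions ----
  cluster_ids <- unique(cluster_tab$cluster_id)
  # fragments overlapping any cluster constituent
  cl_iv <- sort_intervals(cluster_tab[, c("chrom", "start", "end")], layout)
  cl_frag_all <- unique(
    fragments$name[interval_overlaps(fragments, cl_iv,
                                     layout = layout)$pairs$a_idx])

  targets <- lapply(cluster_ids, function(cid) {
    sort(sample(genes$GENE_ID, sample(1:3, 1)))
  })
  names(targets) <- cluster_ids

  ib <- character(0); io <- character(0); isc <- numeric(0)
  add_inter <- function(bait_frag, oe_frag, score) {
    if (bait_frag == oe_frag) return(invisible())
    ib[length(ib) + 1] <<- bait_frag
    io[length(io) + 1] <<- oe_frag
    isc[length(isc) + 1] <<- round(score, 3)
  }
  # one overlap pass maps every fragment to the cluster(s) it touches
  ovcl <- interval_overlaps(fragments, cl_iv, layout = layout)
  cl_sorted_id <- cluster_tab$cluster_id[
    order(match(cluster_tab$chrom, layout$chrom), cluster_tab$start,
          cluster_tab$end)]
  for (j in seq_len(nrow(ovcl$pairs))) {
    oe <- fragments$name[ovcl$pairs$a_idx[j]]
    cid <- cl_sorted_id[ovcl$pairs$b_idx[j]]
    for (gid in targets[[cid]]) {
      add_inter(bait_frag_of_gene(gid), oe, stats::runif(1, 6, 14))
    }
  }
  for (cell in c("MK", "EB")) {
    dd <- disp[[cell]]
    oe_all <- frag_at(dd$chrom, round((dd$start + dd$end) / 2))
    for (i in seq_len(nrow(dd))) {
      oe <- oe_all[i]
      if (oe %in% cl_frag_all) next
      u <- stats::runif(1)
      if (u < 0.5) {
        add_inter(bait_frag_of_gene(sample(genes$GENE_ID, 1)), oe,
                  stats::runif(1, 5, 12))
      } else if (u < 0.75) {
        add_inter(bait_frag_of_gene(sample(genes$GENE_ID, 1)), oe,
                  stats::runif(1, 0.5, 4.5))
      }
    }
  }
  bait_ids <- baits$fragment_id
  if (length(bait_ids) >= 2) {
    for (i in seq_len(30)) {
      pr <- sample(bait_ids, 2)
      if (any(pr %in% cl_frag_all)) next
      add_inter(pr[1], pr[2], stats::runif(1, 5, 12))
    }
  }
  nonbait <- setdiff(fragments$name, c(bait_ids, cl_frag_all))
  for (i in seq_len(50)) {
    add_inter(sample(bait_ids, 1), sample(nonbait, 1),
              stats::runif(1, 0.5, 8))
  }
  inter <- unique(data.frame(bait_id = ib, oe_id = io, score = isc,
                             stringsAsFactors = FALSE))
  fr <- function(id, what) {
    i <- match(id, fragments$name)
    fragments[[what]][i]
  }
  interactions <- data.frame(
    bait_chr = fr(inter$bait_id, "chrom"),
    bait_start = fr(inter$bait_id, "start"),
    bait_end = fr(inter$bait_id, "end"),
    bait_id = inter$bait_id,
    bait_genes = baits$genes[match(inter$bait_id, baits$fragment_id)],
    oe_chr = fr(inter$oe_id, "chrom"),
    oe_start = fr(inter$oe_id, "start"),
    oe_end = fr(inter$oe_id, "end"),
    oe_id = inter$oe_id, score = inter$score, stringsAsFactors = FALSE)
  interactions$bait_genes[is.na(interactions$bait_genes)] <- ""

  # modest expression boost for designated target genes (SE-linked genes
  # sit higher in the FPKM distribution)
  tgt_all <- unique(unlist(targets))
  genes$FPKM[genes$GENE_ID %in% tgt_all] <-
    signif(genes$FPKM[genes$GENE_ID %in% tgt_all] * 3, 3)

  ## ---- variants with planted enrichment ----
  designated <- cluster_tab[cluster_tab$cell == "MK", , drop = FALSE]
  designated <- sort_intervals(designated[, c("chrom", "start", "end")],
                               layout)
  n_var <- cfg$n_platelet + cfg$n_redcell
  trait <- c(rep("platelet", cfg$n_platelet), rep("red_cell", cfg$n_redcell))
  trait <- trait[sample.int(n_var)]
  vid <- sprintf("rs%05d", seq_len(n_var))

  mk_enh_real <- enhancers$MK[enhancers$MK$role != "decoy", , drop = FALSE]
  placement <- sample(c("exonic", "promoter", "enhancer", "uniform"), n_var,
                      replace = TRUE,
                      prob = c(cfg$frac_exonic, cfg$frac_promoter,
                               cfg$frac_in_enhancer,
                               1 - cfg$frac_exonic - cfg$frac_promoter -
                                 cfg$frac_in_enhancer))
  chrv <- character(n_var); posv <- numeric(n_var)
  consequence <- rep("intronic_or_intergenic", n_var)
  vep_gene <- rep("", n_var)
  for (i in seq_len(n_var)) {
    if (placement[i] == "exonic") {
      g <- sample.int(nrow(genes), 1)
      t1 <- as.numeric(strsplit(genes$TSS[g], ";", fixed = TRUE)[[1]][1])
      chrv[i] <- genes$CHR[g]
      posv[i] <- t1 + sample(50:1500, 1)
      consequence[i] <- "exonic_or_splice"
      vep_gene[i] <- genes$GENE_ID[g]
    } else if (placement[i] == "promoter" && nrow(promoters) > 0) {
      p <- sample.int(nrow(promoters), 1)
      chrv[i] <- promoters$chrom[p]
      posv[i] <- promoters$start[p] +
        sample.int(promoters$end[p] - promoters$start[p], 1)
      consequence[i] <- "promoter_overlap_candidate"
    } else if (placement[i] == "enhancer") {
      w <- mk_enh_real$end - mk_enh_real$start
      e <- sample.int(nrow(mk_enh_real), 1, prob = w)
      chrv[i] <- mk_enh_real$chrom[e]
      posv[i] <- mk_enh_real$start[e] + sample.int(w[e], 1)
    } else {
      chrv[i] <- sample(layout$chrom, 1)
      posv[i] <- sample.int(L - 2, 1) + 1
    }
  }
  pts <- data.frame(chrom = chrv, start = posv - 1, end = posv,
                    stringsAsFactors = FALSE)
  in_desig <- interval_overlaps(pts, designated, layout = layout)$hits
  odds0 <- cfg$sig_rate / (1 - cfg$sig_rate)
  odds <- ifelse(in_desig, odds0 * cfg$theta, odds0)
  p_sig <- odds / (1 + odds)
  significant <- stats::runif(n_var) < p_sig
  pval <- ifelse(significant,
                 signif(stats::runif(n_var) * cfg$sig_magnitude, 6),
                 signif(stats::runif(n_var), 6))
  variants <- data.frame(ID = vid, CHR = chrv, POS = posv, TRAIT = trait,
                         PVAL = pval, CONSEQUENCE = consequence,
                         VEP_GENE = vep_gene, stringsAsFactors = FALSE)

  ## ---- LD proxies ----
  n_prox <- stats::rpois(n_var, cfg$proxies_mean)
  ld_rows <- list()
  for (i in seq_len(n_var)) {
    if (n_prox[i] == 0) next
    off <- round(stats::runif(n_prox[i], -cfg$ld_window, cfg$ld_window))
    ppos <- pmin(L - 1, pmax(1, posv[i] + off))
    u <- stats::runif(n_prox[i])
    r2 <- ifelse(u < 0.2, 1,
                 ifelse(u < 0.7, round(stats::runif(n_prox[i], 0.8, 1), 4),
                        round(stats::runif(n_prox[i], 0.3, 0.8), 4)))
    ld_rows[[length(ld_rows) + 1]] <- data.frame(
      SENTINEL_ID = vid[i],
      PROXY_ID = sprintf("%s_p%d", vid[i], seq_len(n_prox[i])),
      PROXY_CHR = chrv[i], PROXY_POS = ppos, R2 = r2,
      stringsAsFactors = FALSE)
  }
  ld <- if (length(ld_rows)) do.call(rbind, ld_rows) else
    data.frame(SENTINEL_ID = character(), PROXY_ID = character(),
               PROXY_CHR = character(), PROXY_POS = numeric(),
               R2 = numeric(), stringsAsFactors = FALSE)

  ## ---- truth record ----
  truth <- list(
    peaks = data.frame(mk_peaks,
                       HSC = pat_mk$flags[, "HSC"] == 1,
                       CMP = pat_mk$flags[, "CMP"] == 1,
                       MEP = pat_mk$flags[, "MEP"] == 1,
                       EB = pat_mk$flags[, "EB"] == 1,
                       category = pat_mk$category,
                       stringsAsFactors = FALSE),
    clusters = cluster_tab,
    targets = data.frame(
      cluster_id = rep(names(targets), lengths(targets)),
      GENE_ID = unlist(targets, use.names = FALSE),
      stringsAsFactors = FALSE),
    designated = designated,
    variants = data.frame(ID = vid, in_designated = in_desig,
                          significant = significant,
                          stringsAsFactors = FALSE),
    decoy_enhancers = decoy_enh)
  rownames(truth$targets) <- NULL

  structure(list(layout = layout, peaks = peaks, ctcf = ctcf,
                 cd34_h3k27ac = cd34, enhancers = enhancers,
                 promoters = promoters, signal = signal,
                 fragments = fragments, genes = genes, baits = baits,
                 interactions = interactions, variants = variants, ld = ld,
                 truth = truth, config = cfg),
            class = "synthetic_dataset")
}
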