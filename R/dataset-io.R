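#' Write a synthetic dataset to a directory of plain-text files
#'
#' Emits every component in the format its consuming stage reads: a
#' chromosome-sizes file, BED/BED4 peak and segment files, bedGraph signal
#' tracks, TSV tables (genes, variants, LD, interactions) and the truth
#' record, plus a `manifest.tsv` mapping file to role.
#'
#' @param dataset A `synthetic_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The manifest data.frame (`file`, `role`), invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- list()
  emit <- function(file, role, writer) {
    writer(file.path(dir, file))
    man[[length(man) + 1]] <<- data.frame(file = file, role = role,
                                          stringsAsFactors = FALSE)
  }
  ds <- dataset
  emit("chrom.sizes", "genome_layout",
       function(p) write_chrom_sizes(ds$layout, p))
  for (cell in names(ds$peaks)) {
    emit(paste0("peaks_", cell, ".bed"), paste0("open_chromatin_", cell),
         local({ cc <- cell; function(p) write_bed(ds$peaks[[cc]], p) }))
  }
  emit("ctcf_MK.bed", "ctcf_peaks", function(p) write_bed(ds$ctcf, p))
  emit("cd34_h3k27ac.bed", "progenitor_h3k27ac",
       function(p) write_bed(ds$cd34_h3k27ac, p))
  for (cell in names(ds$enhancers)) {
    emit(paste0("enhancers_", cell, ".bed"),
         paste0("enhancer_segments_", cell),
         local({ cc <- cell; function(p) write_bed(ds$enhancers[[cc]], p) }))
  }
  emit("promoters.bed", "promoter_segments",
       function(p) write_bed(ds$promoters, p))
  for (cell in names(ds$signal)) {
    emit(paste0("h3k27ac_", cell, ".bedgraph"),
         paste0("h3k27ac_treatment_", cell),
         local({ cc <- cell
           function(p) write_bedgraph(ds$signal[[cc]]$treatment, p) }))
    emit(paste0("input_", cell, ".bedgraph"),
         paste0("h3k27ac_input_", cell),
         local({ cc <- cell
           function(p) write_bedgraph(ds$signal[[cc]]$input, p) }))
  }
  emit("fragments.bed", "restriction_fragments",
       function(p) write_bed(ds$fragments, p))
  emit("genes.tsv", "genes", function(p) write_genes(ds$genes, p))
  emit("interactions.tsv", "pchic_interactions",
       function(p) write_interactions(ds$interactions, p))
  emit("variants.tsv", "sentinel_variants",
       function(p) write_variants(ds$variants, p))
  emit("ld.tsv", "ld_proxies", function(p) write_ld(ds$ld, p))

  tr <- ds$truth
  emit("truth_peaks.tsv", "truth_peak_categories", function(p) {
    x <- tr$peaks
    x$start <- format_bp(x$start); x$end <- format_bp(x$end)
    write_tsv_plain(x, p)
  })
  emit("truth_clusters.tsv", "truth_se_clusters", function(p) {
    x <- tr$clusters
    x$start <- format_bp(x$start); x$end <- format_bp(x$end)
    write_tsv_plain(x, p)
  })
  emit("truth_targets.tsv", "truth_cluster_targets",
       function(p) write_tsv_plain(tr$targets, p))
  emit("truth_designated.bed", "truth_designated_regions",
       function(p) write_bed(tr$designated, p))
  emit("truth_variants.tsv", "truth_variant_significance",
       function(p) write_tsv_plain(tr$variants, p))
  emit("truth_decoys.bed", "truth_decoy_enhancers",
       function(p) write_bed(tr$decoy_enhancers, p))

  manifest <- do.call(rbind, man)
  write_tsv_plain(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}

#' Read a written synthetic dataset back through the module readers
#'
#' @param dir Directory produced by [write_dataset()].
#' @return A list shaped like the output of [simulate_dataset()] (without
#'   `config`; `truth` as read from the truth files).
#' @export
read_dataset <- function(dir) {
  layout <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  rb <- function(f) read_bed(file.path(dir, f), layout)
  cells <- c("MK", "EB", "HSC", "CMP", "MEP")
  peaks <- lapply(cells, function(cc) rb(paste0("peaks_", cc, ".bed")))
  names(peaks) <- cells
  enh <- lapply(c("MK", "EB"), function(cc)
    rb(paste0("enhancers_", cc, ".bed")))
  names(enh) <- c("MK", "EB")
  signal <- lapply(c("MK", "EB"), function(cc) {
    list(treatment = read_bedgraph(
           file.path(dir, paste0("h3k27ac_", cc, ".bedgraph")),
           layout = layout),
         input = read_bedgraph(
           file.path(dir, paste0("input_", cc, ".bedgraph")),
           layout = layout))
  })
  names(signal) <- c("MK", "EB")
  genes <- read_genes(file.path(dir, "genes.tsv"))
  fragments <- rb("fragments.bed")
  truth <- NULL
  if (file.exists(file.path(dir, "truth_peaks.tsv"))) {
    tpk <- read_tsv_checked(file.path(dir, "truth_peaks.tsv"),
                            c("chrom", "start", "end", "category"))
    tpk$start <- as.numeric(tpk$start); tpk$end <- as.numeric(tpk$end)
    tcl <- read_tsv_checked(file.path(dir, "truth_clusters.tsv"),
                            c("cluster_id", "cell", "chrom", "start", "end"))
    tcl$start <- as.numeric(tcl$start); tcl$end <- as.numeric(tcl$end)
    truth <- list(
      peaks = tpk, clusters = tcl,
      targets = read_tsv_checked(file.path(dir, "truth_targets.tsv"),
                                 c("cluster_id", "GENE_ID")),
      designated = rb("truth_designated.bed"),
      variants = read_tsv_checked(file.path(dir, "truth_variants.tsv"),
                                  c("ID", "in_designated", "significant")),
      decoy_enhancers = rb("truth_decoys.bed"))
  }
  list(layout = layout, peaks = peaks, ctcf = rb("ctcf_MK.bed"),
       cd34_h3k27ac = rb("cd34_h3k27ac.bed"), enhancers = enh,
       promoters = rb("promoters.bed"), signal = signal,
       fragments = fragments, genes = genes,
       baits = make_baits(fragments, genes, layout),
       interactions = read_interactions(file.path(dir, "interactions.tsv")),
       variants = read_variants(file.path(dir, "variants.tsv")),
       ld = read_ld(file.path(dir, "ld.tsv")),
       truth = truth)
}
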