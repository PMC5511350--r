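# mkregmap

Linking non-coding GWAS variants for platelet traits to the genes they
most probably regulate, through the regulatory landscapes of
megakaryocytes (MKs, the platelet-producing cell) and erythroblasts (EBs).

Most sentinel variants for platelet count, mean platelet volume, platelet
distribution width and plateletcrit fall outside coding sequence. Their
target genes are usually not the nearest ones: enhancers act on promoters
through chromatin loops. `mkregmap` implements, as a tested and reusable R
package, the computational pipeline needed to close that gap with
cell-type-matched epigenomes:

* **Opening dynamics** — classify a terminal cell's open-chromatin peaks by
  their presence (minimum 1 bp overlap) across the differentiation
  hierarchy HSC → CMP → MEP → MK/EB into categories I–IV (I open in all
  five cell types, II closed in the sister lineage, III/IV opened only at
  the final step), the remainder reported as uncategorized.
* **Super-enhancer (SE) calling** — remove enhancers within 1 kb of
  promoter states, stitch survivors within 12.5 kb, score each region by
  background-subtracted H3K27ac signal
  (`max(0, treatment − input)` over the region), and split SEs from
  typical enhancers (TEs) where a unit-slope tangent touches the scaled
  ascending rank–score curve.
* **PCHi-C gene mapping** — restriction fragments, TSS-bearing bait
  fragments, and interaction queries at CHiCAGO-like score ≥ 5, honouring
  bait–bait links in both directions and ignoring bait→prey links from a
  queried bait.
* **Tiered variant→gene assignment** — coding → promoter (±1 kb, TSS
  required) → exonic-in-enhancer (+ bait genes) → fragment interactions →
  LD proxy cascade at r² = 1 / ≥ 0.9 / ≥ 0.8 → baits ±10 kb → unassigned.
* **Circular genomic permutation** — rotate the genome-ordered P-value
  vector against fixed variant positions (chromosome 1 follows the last
  chromosome), recompute an enrichment statistic per rotation, and report
  the add-one empirical P: rank / (shifts + 1), never zero; 999,999
  shifts by default.

Because the study data this pipeline is designed for are controlled
access, the package ships a deterministic synthetic-study generator
(`simulate_dataset()`) that emulates the data structures — planted SE
clusters at ≥ 10× enhancer signal, hierarchically opening peaks,
a HindIII-like fragment grid, promoter-anchored interactions with
designated target genes, and variant sets with block LD and a planted
significance enrichment (odds × θ inside MK-specific SE constituents).
Every stage is tested against the generator's truth record and against
independent brute-force oracles.

## Worked example

```r
library(mkregmap)

ds <- simulate_dataset(sim_config(seed = 1))

filt <- filter_promoter_enhancers(
  ds$enhancers$MK[, c("chrom", "start", "end", "name")],
  ds$promoters, pad = 1000, layout = ds$layout)
se <- call_superenhancers(filt, ds$signal$MK$treatment,
                          ds$signal$MK$input, exclude = ds$promoters,
                          layout = ds$layout)

enr <- se_te_variant_enrichment(
  ds$variants,
  se$constituents[se$constituents$is_super, c("chrom", "start", "end")],
  se$constituents[!se$constituents$is_super, c("chrom", "start", "end")],
  ds$layout)

perm <- circular_permutation_test(
  ds$variants,
  se$constituents[se$constituents$is_super, c("chrom", "start", "end")],
  ds$layout, mode = "hypergeom_tail", sig_threshold = 5e-8,
  n_shifts = 999999, seed = 7)
```

which prints (seed 1):

```
12 super enhancers from 212 stitched regions; 77 SE constituents, 200 typical enhancers
SE/TE enrichment: OR = 2.48, two-sided exact P = 0.00176
Circular permutation test (hypergeom_tail)
  variants: 800  shifts: 999999
  observed statistic: 0.005370389
  rank: 5136  empirical P: 0.005136
```

The 12 called SEs are exactly the 12 planted clusters; sentinel variants
are enriched in SE constituents relative to TEs (cross-product odds ratio
2.48), and the permutation test places the observed in-SE significance in
the top 0.5% of 999,999 genome rotations, while the same test on typical
enhancers is null (empirical P ≈ 0.65).

## Analysis workflow

The `analysis/` scripts run the study end to end, writing tables under
`results/analysis/`:

```sh
Rscript analysis/01_simulate.R        # synthetic study to results/analysis/data
Rscript analysis/02_dynamics.R        # opening categories I-IV per MK peak
Rscript analysis/03_superenhancers.R  # SE calling MK + EB, overlap, opening trace
Rscript analysis/04_map_genes.R       # enhancer-gene links, connectivity, fragments
Rscript analysis/05_assign_variants.R # tiered assignment + summary
Rscript analysis/06_enrichment.R      # Fisher SE/TE + circular permutation
```

`run_all(pipeline_config(out_dir, seed))` performs the same stages in one
call with every parameter at its study default (±500 bp, ±1 kb, 12.5 kb,
score ≥ 5, r² cascade 1/0.9/0.8, ±10 kb, 5e-8, 999,999 shifts) and writes
a manifest with md5 content hashes; identical config + seed reproduces
identical hashes.

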