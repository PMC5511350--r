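---
title: "Mapping platelet-trait variants through megakaryocyte regulatory landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping platelet-trait variants through megakaryocyte regulatory landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Most GWAS variants for platelet traits (count, mean volume, distribution
width, crit) are non-coding, so the gene each variant influences cannot be
read off the coordinates. `mkregmap` implements the computational pipeline
that links such variants to candidate target genes using cell-type-matched
epigenomes of the megakaryocyte (MK) lineage: open-chromatin dynamics across
the differentiation hierarchy (HSC to CMP to MEP to MK, with erythroblasts,
EB, as the sister lineage), super-enhancer (SE) calling from H3K27ac,
promoter capture Hi-C (PCHi-C) interactions, a tiered variant-to-gene
assignment, and a circular genomic permutation enrichment test. This
vignette documents the models, the tunable parameters, the synthetic study
generator used for testing, and the numerical choices a maintainer should
know about.

## Opening-dynamics classification

Each open-chromatin peak of the reference terminal cell is overlapped
(minimum 1 bp, half-open coordinates) with peaks of HSCs, CMPs, MEPs and
the other terminal cell, giving a 4-bit presence pattern. Four patterns are
named: category I `(1,1,1,1)` (open throughout), II `(1,1,1,0)` (closes in
the sister lineage), III `(0,0,0,0)` (opens only in the reference cell at
the final step) and IV `(0,0,0,1)` (opens in both terminal cells). The 12
remaining patterns are reported as UNCATEGORIZED with their pattern
retained, so the uncategorized remainder stays auditable. CTCF labels use
unpadded peak coordinates; enhancer-state and progenitor-acetylation labels
pad peaks by 500 bp first, because open-chromatin summits and flanking
H3K27ac are systematically offset — no such offset argument applies to
CTCF, which binds inside the accessible site. Whether the sister-terminal
column should also be padded is not decidable from first principles; we use
the unpadded 1 bp rule for all presence columns, consistent with the
progenitor overlap definition.

## Super-enhancer calling

Enhancer-state segments overlapping promoter-like states (promoter, weak
promoter, bivalent promoter) padded by 1 kb are removed outright, so that
promoter acetylation cannot inflate enhancer scores. Survivors are stitched
when separated by at most 12,500 bp, measured as `start_next - end_prev`
(bases strictly between segments; touching segments always stitch). Each
stitched or single region is scored as

```
score = max(0, signal_sum(H3K27ac) - signal_sum(input))
```

where `signal_sum` integrates per-bp density over the region, skipping
excluded bases (promoters, blacklist) and applying each track's scale
factor. Scores are floored at zero: negative background-subtracted signal
is noise for ranking purposes. The SE threshold is the classic rank-curve
geometry: sort scores ascending, scale rank and score to `[0, 1]`, and take
the index maximizing `x - y`, which is where a unit-slope tangent touches
the curve; regions scoring strictly above the unscaled cutoff are SEs,
their members SE constituents, all other members typical enhancers (TEs).
Numerical details that matter:

* Score ties are broken by genomic position (earlier chromosome/start ranks
  better) so ranking is a strict total order and reruns are identical.
* A constant score vector scales to `y = 0`; the tangent lands on the last
  index and *no* region exceeds the cutoff — constant data yields no SEs.
* Fewer than 3 stitched regions: the curve is degenerate, no SE is called,
  and a warning is emitted.
* Scoring uses total background-subtracted signal per region (not density
  per bp). Density weighting would penalize long stitched clusters, which
  is exactly what SE calling should not do; a density mode was considered
  and rejected for the default.
* Multiplying treatment and input by a common factor rescales all scores
  linearly and leaves the SE/TE partition unchanged (tested).

Cross-cell-type comparison marks an SE "shared" when it overlaps an SE of
the other cell type by at least 50% of *either* region's length. A
reciprocal ("both lengths") reading is stricter; the either-length reading
is the most inclusive symmetric interpretation and the fraction is a
parameter (`min_frac`) for sensitivity analysis.

## PCHi-C gene mapping

Restriction fragments tile each chromosome; baits are fragments containing
at least one annotated TSS and carry those genes. A query region collects
the genes of every bait interacting at score >= 5 (inclusive — "at least
5") with any fragment the region overlaps. When the overlapped fragment is
itself a bait, bait-bait interactions stored in either direction
contribute the partner bait's genes; interactions from the overlapped bait
*out* to a non-bait prey contribute nothing, since the captured signal
belongs to the bait side. Multi-gene baits contribute all their genes. The
same score threshold is applied to bait-bait interactions as to
bait-prey interactions; nothing in the protocol suggests a different
cutoff.

## Tiered variant assignment

Variants are assigned by the first succeeding rule, in order: `coding`
(expressed exonic/splice variant outside enhancers keeps its VEP gene; a
gene with FPKM < 1 counts as not expressed), `promoter` (variant inside a
promoter state padded 1 kb that contains a TSS; the assigned genes are
those whose TSS lies in the padded segment, not the nearest gene),
`enhancer_plus_bait` (exonic variant inside an enhancer keeps its gene and
adds interacting bait genes), `fragment_interaction` (genes of baits
interacting with the variant's fragment), the LD cascade
(`ld_r2_1`, `ld_r2_09`, `ld_r2_08`: proxies at r^2 = 1, then >= 0.9, then
>= 0.8 re-run the non-coding rules; within one level the gene sets of all
qualifying proxies are unioned, and the first non-empty level stops the
cascade), `bait_10kb` (genes of baits whose fragment padded 10 kb covers
the variant — compensating for the known insensitivity of capture Hi-C to
short-range interactions), else `unassigned` — emitted, never dropped.
Two readings of the exonic-variant side rules were possible; we resolved
them as: exonic variants in enhancers keep the gene *and* add bait genes,
while exonic variants of unexpressed genes fall through to the promoter
and interaction logic without keeping their gene. Gene distances use the
mean TSS position when a gene has several TSSs.

The SE-versus-TE variant enrichment builds a 2x2 table of elements bearing
at least one sentinel versus none (SE constituents versus TEs), reports
the cross-product odds ratio `ad/bc` and a two-sided conditional exact
P-value. Counting elements rather than base pairs is the primary mode; a
bp-normalized variant (counts against kb of element length) is available
behind `by = "bp"` because the choice is genuinely open.

## Circular genomic permutation

Variants are ordered by karyotype chromosome order then position (ties by
id); the vector of association P-values is rotated against the fixed
variant positions, trait labels and region memberships, with the first
chromosome following the last. Rotation preserves both the multiset of
P-values and the spacing of significant hits, so the null respects local
LD-induced correlation. Three per-dataset statistics are provided because
the procedure's verbal description is ambiguous: `count` (significant
foreground-trait variants inside the region set), `hypergeom_tail` (upper
tail probability of at least that count under a hypergeometric draw —the
"how likely is it to see at least the observed number" reading), and
`trait_contrast` (one-sided exact test of foreground versus background
trait among significant variants, inside versus outside the region set),
the default, since the published contrast is platelet versus red-cell
variants within the same region class. The empirical P uses the add-one
rule: rank = 1 + number of shifted statistics at least as extreme (ties
count as extreme), divided by shifts + 1, so P is never zero and with
999,999 shifts equals the rank over 1,000,000. Offsets are sampled
uniformly with replacement from `1..n-1`; an exhaustive mode enumerates
every non-zero rotation once and is what the oracle tests exercise. The
`count` statistic is integer-valued and heavily tied, which makes its
empirical P conservative by construction; calibration properties are
therefore stated for the near-continuous tail statistics.

## The synthetic study generator

Real data of this kind are controlled-access, so the package carries a
deterministic generator (`simulate_dataset()`) that emulates the
*structure* of the study at desk scale; all statistical guarantees below
are statements about this generator, not about any real cohort.

* **Layout.** Features (SE clusters, dispersed enhancers, genes with
  promoter segments, decoy promoter-proximal enhancers, extra peaks) are
  placed with at least ~12.6 kb between features, so planted clusters and
  only they survive 12.5 kb stitching, and dispersed enhancers stay
  singletons. Default genome: 4 chromosomes of 4 Mb.
* **Signal.** Cluster constituents carry 15-25 units/bp of H3K27ac against
  1.0-1.4 for dispersed enhancers (>= 10x separation) over an input of
  0.05-0.15, making the planted SE set the unique rank-curve answer; the
  deliberately narrow TE value spread keeps the top TE score gap well
  below one rank-curve step, so the tangent cutoff is stable.
* **Fragments.** Lengths are exponential around 4 kb, truncated to
  [0.5 kb, 10 kb]; the upper truncation keeps any single fragment from
  bridging two features placed >= 12.6 kb apart, which in turn keeps
  cluster-fragment interactions exactly recoverable.
* **Interactions.** Every fragment overlapping a planted cluster links to
  that cluster's 1-3 designated target genes at score 6-14; dispersed
  enhancers link to random baits (half at score >= 5, a quarter below
  threshold); noise and bait-bait interactions avoid cluster fragments so
  the truth record exactly determines gene recovery.
* **Opening patterns.** Peak categories are drawn at the fractions
  I/II/III/IV = 0.38/0.15/0.20/0.147 (remainder uncategorized, drawn
  uniformly from the 12 unnamed patterns), chosen so category I carries
  roughly its observed share and the categorized total sits near 88% of
  peaks; progenitor peak sets are jittered copies (+-100 bp on a >= 400 bp
  body) of flagged peaks, so recovered patterns equal planted ones
  exactly.
* **Variants.** Defaults: 400 platelet + 400 red-cell sentinels; 30% are
  placed inside enhancer bases (matching the observed ~32% of non-coding
  sentinels in regulatory elements), 8% exonic near a TSS, 5% in promoter
  segments, the rest uniform. A variant's odds of being "significant"
  (P ~ U(0, 1e-9), versus U(0,1) otherwise) are baseline odds
  (rate 0.15) multiplied by `theta` when it lies inside the designated set
  (MK-specific SE constituents), for any trait — `theta = 1` removes the
  enrichment entirely and `theta = 0` annihilates significance inside the
  set. The default `theta = 5` mirrors the scale of the reported SE/TE
  odds ratio. LD proxies (Poisson mean 3 per sentinel) sit within 25 kb,
  with r^2 drawn as 20% exactly 1, 50% U(0.8, 1), 30% U(0.3, 0.8).
* **Determinism.** One seed governs every draw; identical config + seed
  reproduces byte-identical files.

What the generator does *not* emulate: nucleotide sequence, read-level
noise, realistic coalescent LD (block-structured toy LD only), distance
decay of contact frequency, and the genome-scale feature density of a real
karyotype. Passing tests therefore demonstrate algorithmic correctness and
calibration under the planted model, not performance on cohort data; the
study's published headline counts are not reproducible at this scale and
are not targeted.

## Problem sizes and test design

The suite checks every interval, stitching, scoring, mapping and ranking
operation against independent brute-force oracles (quadratic overlap
scans, transitive-closure clustering, per-base signal sums, explicit
rotation nulls, full hypergeometric enumeration). Distributional checks
use: type-I error of the permutation test at theta = 1 over 500 generator
replicates with 999 shifts each (rejection at 0.05 expected in
[0.03, 0.07]); power/direction at theta = 5 with 200 variants over 100
replicates (the MK-specific-SE empirical P must undercut the
typical-enhancer one in >= 90%). The exact-test oracle covers every 2x2
table with row margins up to 12 exhaustively plus one randomized table per
margin pair up to (50, 50). These sizes keep the whole suite and the
acceptance script within a few minutes on one core while leaving the
statistical bands comfortably identifiable.

## Known limitations

* Promoter assignment requires a TSS inside the padded promoter state;
  promoter states without an annotated TSS assign nothing by design.
* LD proxies carry no consequence annotation, so proxy re-runs use only
  the non-coding rules.
* The bp-normalized enrichment mode discretizes element length to whole
  kb and is intended for sensitivity analysis, not inference.
* `se_overlap` marks sharing from single pairs; chains of partial overlaps
  are not merged into shared "families".
* The permutation test assumes variants are exchangeable under rotation of
  the P-value vector; planted placement enrichment (variants preferring
  enhancers) is part of the fixed structure and is correctly conditioned
  on, but real fine-scale correlation between placement and significance
  beyond LD is not modelled.
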