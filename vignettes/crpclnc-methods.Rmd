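---
title: "Methods: discovering androgen-regulated lncRNAs upregulated in CRPC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering androgen-regulated lncRNAs upregulated in CRPC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crpclnc)
```

## The problem

Castration-resistant prostate cancer (CRPC) grows despite androgen
deprivation, typically with restored androgen-receptor (AR) signalling.
Long non-coding RNAs (lncRNAs) that are specifically abundant in CRPC and
sit under direct AR control are candidate drivers and biomarkers. `crpclnc`
implements a transcriptome-wide screen for such lncRNAs from three inputs a
sequencing core routinely produces: gene models (GTF), read-count matrices
with sample sheets, and AR ChIP-seq peak sets (BED). The screen has five
stages:

1. **Quantify** — counts are normalized to RPKM,
   $\mathrm{RPKM}_{gs} = 10^9 \, c_{gs} / (L_g \, N_s)$, with $L_g$ the
   summed exon length of gene $g$ and $N_s$ the library size of sample $s$.
2. **Classify** — genes up in CRPC tissues are split into **Type_A**
   (significantly up versus both benign prostate and localized prostate
   cancer) and **Type_B** (up versus benign only, Type_A removed).
3. **Curate** — database lncRNAs whose exons coincide with protein-coding
   exons are removed; the rest are classified antisense / intergenic /
   other by genomic context.
4. **Integrate** — AR ChIP-seq peaks are assigned to genes by TSS
   proximity and combined with androgen (DHT) induction and AR-knockdown
   (siAR) fold changes to call AR-regulated genes.
5. **Report** — the candidate funnel (CRPC-upregulated lncRNAs →
   AR/androgen-regulated → AR-bound near the TSS) and a ranked candidate
   table.

## Differential testing

Group sizes in this design are small (benign $n=6$, localized cancer
$n=8$, CRPC $n=6$), so the Mann–Whitney $U$ test is computed **exactly**:
for $n_1+n_2 \le 20$ the null distribution of the rank sum over all
$\binom{n_1+n_2}{n_1}$ group assignments is obtained with a shift-algorithm
dynamic program over midrank sums, which handles ties correctly. The
two-sided p-value is the probability of a $U$ at least as far from
$n_1 n_2/2$ as observed; at the study's sizes the smallest achievable value
is $2/3003 \approx 6.7\times10^{-4}$ (6 vs 8) and $2/924$ (6 vs 6). Larger
designs fall back to the tie-corrected normal approximation with
continuity correction. The test suite checks both branches against full
enumeration and `stats::wilcox.test`.

Three deliberate choices:

* **Two-sided test plus a direction** taken from the median difference,
  rather than a one-sided test. A single significance criterion plus an
  explicit direction is the conservative reading of "upregulated with
  $P < 0.05$".
* **No multiple-testing correction by default.** The screen's published
  criterion is nominal $P < 0.05$; reproducing it faithfully matters more
  here than error-rate optimality, and the acceptance suite shows the
  realized false-call rate on a null cohort stays below the nominal level
  (the discrete exact test is conservative). `classify_genes(adjust =
  "BH")` enables Benjamini–Hochberg for users who want it.
* **The expression filter is the CRPC group mean** RPKM exceeding the
  per-database cutoff (RefSeq 5, GENCODE 1, NONCODE 1). The filter is
  deliberately database-specific: RefSeq models are fewer and better
  supported, so a stricter cutoff is used there. "Mean" matches how
  per-group expression is reported in the candidate table.

Whether Type_A genes should additionally be higher in localized cancer
than benign is left unconstrained; the definition only compares CRPC
against each of the other groups.

## Peak-to-gene assignment

Distance is **interval-to-point**: 0 when the TSS lies inside the peak,
otherwise the gap to the nearer peak edge. This is robust to peak width; a
TSS under a peak is unambiguously bound. Two conventions are exposed:

* **AR-target calling (50 kb window, protein-coding genes):** each peak
  counts only for its closest-TSS gene(s) — ties keep all tied genes, so
  the result is deterministic without arbitrary ordering — and a gene is
  bound when an assigned peak lies within the window. The conjunction
  ("closest gene" *and* "within 50 kb") is the stricter of the two readings
  of the published workflow; `closest_only = FALSE` relaxes it to
  window-only. AR targets are genes bound *and* responsive (induced or
  repressed) in a line's contrast; the androgen-dependent lines (LNCaP,
  VCaP) are summarized by their intersection, the CRPC-model line (22Rv1)
  separately. This stage is restricted to protein-coding genes, mirroring
  the RefSeq-gene basis of that analysis; lncRNAs are handled by the
  funnel.
* **lncRNA funnel (10 kb window):** binding "in the vicinity of the TSS"
  is a plain within-window criterion over the union of the cell lines'
  peak sets — a candidate lncRNA's TSS often sits inside a host or
  neighbouring gene, so nearest-gene assignment would be misleading here.

Fold changes are $(\bar{x}_{\mathrm{treated}} + \varepsilon) /
(\bar{x}_{\mathrm{control}} + \varepsilon)$ on RPKM with a symmetric
pseudocount $\varepsilon = 0.01$ (so an all-zero gene has fold 1), and the
cutoffs are **strict** inequalities exactly as specified: induced
$> 1.5$, repressed $< 0.8$; for the siAR contrast the reading inverts
(knockdown lowering a gene marks it AR-induced). $\varepsilon$ only
matters for genes expressed near zero; at RPKM 1 it shifts folds by about
1%.

## lncRNA curation

With directional (stranded) libraries, reads from opposite strands are
distinguishable; exclusion therefore requires **same-strand** exonic
overlap (≥ 1 bp by default) with a protein-coding gene — an antisense
lncRNA overlapping coding exons on the other strand is kept. Because the
original curation was done by eye on a genome browser, the minimum overlap
fraction that should trigger exclusion is not knowable; it is exposed as
`min_overlap_frac` (default 0, i.e. any shared exonic base excludes).
Context of kept candidates uses gene-*body* overlap: antisense (opposite
strand overlap, checked first), intergenic (no overlap on either strand),
other (same-strand body overlap without shared exons — sense/intronic
cases). The three contexts plus exclusion partition every candidate.

## Coordinate conventions

Internally everything is 0-based half-open; GTF (1-based inclusive) is
converted on read/write and BED passes through natively, so the round-trip
is exact and off-by-one drift cannot accumulate between modules. The TSS
is strand-aware (`start` on `+`, `end - 1` on `-`). The three source
databases are modelled as a `database` tag on each gene in one merged GTF
rather than three files; a transcript present in two databases must be
pre-resolved to one tag. ChIP-seq peaks are unstranded.

## The synthetic cohort generator

Real patient and cell-line data for this design are controlled-access, so
the package ships a seeded generator whose output exercises every stage
against a known ground truth. What it emulates:

* the tissue design (6/8/6) with negative-binomial counts,
  $\mathrm{mean} = \mathrm{RPKM}_{\mathrm{target}} \times L_g/10^3 \times
  N_s/10^6$, dispersion 0.1 (a typical bulk RNA-seq value; both are
  config fields since the original tissues carry no published noise
  model). Library sizes are drawn uniformly from 20–30 M reads;
* planted Type_A genes (CRPC mean raised 6-fold over both groups), Type_B
  genes (CRPC and localized cancer raised together over benign), and null
  genes;
* cell-line contrasts with planted treated/control folds (DHT 2.5-fold,
  siAR 0.4-fold for AR-induced genes, reciprocals for repressed);
* AR peaks planted at exact TSS offsets — 49 kb (inside the 50 kb window)
  and 51 kb (outside) for coding genes, 8 kb / 15 kb around the 10 kb
  lncRNA window — plus bound-but-unregulated and regulated-but-unbound
  genes, and decoy peaks placed in a reserved gene-free zone farther than
  the window from every TSS;
* antisense lncRNAs nested opposite-strand inside coding hosts,
  intergenic lncRNAs more than 10 kb from any coding gene, and exonic
  decoys that copy a host's exons on the same strand (which curation must
  exclude).

Gene placement uses per-gene clearances so that a planted peak is closer
to its own gene's TSS than to any other and farther than the AR-target
window from every foreign TSS; with the default 49/51 kb offsets this
needs roughly 110 kb of clearance per peak-bearing gene, which is why the
default chromosome length is 12 Mb for 2 chromosomes. Every emitted peak
is re-verified by an exhaustive peak-by-TSS scan before the generator
returns, and infeasible requests abort with a generation error.

Two separation regimes:

* **`complete`** rejection-samples each gene until its realized data
  respect the planted label: up-genes' minimum CRPC RPKM exceeds the
  comparison groups' maximum (giving the deterministic minimum exact
  p-value), planted folds land strictly past their cutoff, unregulated
  genes land inside the unchanged band, and null genes are re-drawn until
  neither comparison reaches a significant "up" call at the design's
  $\alpha$. This makes ground truth exactly recoverable, which is what
  recovery tests need: any mismatch is a pipeline defect, not noise.
* **`noisy`** draws once with no constraint, and is the honest regime for
  error-rate measurements (type-I control is measured on a noisy null
  cohort of 2,000 genes).

What the generator does **not** emulate — and hence what passing tests do
not show about real data: alignment and counting artifacts, batch and
purity effects in tissues, isoform structure (one transcript per gene),
AR-V7 versus full-length AR, correlated genes, and peak-calling noise.
Recovery at complete separation demonstrates correctness of the decision
logic, not statistical power on real cohorts.

## Problem sizes and runtime

The shipped tests run the generator at 60–330 genes (plus a 2,000-gene
null cohort), 1,000 random instances for the interval oracle, 500 random
designs for the exact-test oracle, and complete the whole suite in well
under a minute of CPU per heavy file. These sizes were chosen as the
smallest at which every planted structure (both peak offsets, all three
lncRNA contexts, a non-trivial funnel) is present with several instances
each.

## Known limitations

* The final published step — dropping candidates already reported in the
  literature — is a manual novelty judgement and is out of scope; the
  funnel output corresponds to the pre-novelty candidate list.
* Enrichment analyses (KEGG/GO via external services), survival
  correlation, and peak calling are out of scope.
* `read_gtf` expects the package's own attribute schema (`gene_id`,
  `gene_name`, `biotype`, `database`); general GENCODE GTFs need their
  biotypes mapped to `coding`/`noncoding` and a `database` tag added
  upstream.
* The exact test enumerates up to $n_1+n_2 = 20$; beyond that the normal
  approximation is standard but approximate.
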