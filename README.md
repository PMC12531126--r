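# clonetrace

Tracing metastatic spread in multiregionally sampled solid tumors from
copy-number and targeted-sequencing data.

## The problem

When a patient's primary tumor and metastases are each sampled in several
anatomical locations, the genetic alterations shared and private to those
samples encode the history of spread: which subclone seeded which site,
whether a metastasis diverged before or after the primary tumor's most
recent common ancestor (MRCA), whether one or several lineages colonized
a site, and whether tumor cells traveled between metastases. This matters
most in tumors profiled from formalin-fixed archival material — such as
pediatric neuroblastoma, Wilms tumor, and gonadal tumors — where
high-coverage sequencing is impractical and large chromosomal alterations
carry the phylogenetic signal.

`clonetrace` implements the full chain of inference:

1. **Clone fractions.** Each segment's log2 ratio (or mirrored B-allele
   frequency, for copy-number-neutral imbalances) is inverted through its
   mixture model to a *mutated sample fraction*,
   `MSF = (Np·2^log2R − Np)/(Nt − Np)`, purity (TCF) is estimated from
   the clearly clonal alterations, and `MCF = MSF/TCF` gives the fraction
   of tumor cells carrying each alteration; MCFs inside
   `(TCF ± 2·SD_MSF)/TCF` are clonal (set to 1). Targeted-sequencing
   variants pass quality and multi-caller consensus filters and convert
   via `MCF = VAF·(CN1·TCF·f1 + CN2·(TCF − TCF·f2) + 2(1 − TCF))/(M·TCF)`.
2. **Subclonal deconvolution.** Events sharing an MCF profile across
   samples were acquired on one branch; measurement-error-aware profile
   clustering and pigeonhole nesting turn the per-sample MCFs into
   subclones with per-sample fractions and a binary subclone × event
   matrix.
3. **Phylogeny.** An exact (branch-and-bound) maximum-parsimony tree over
   the matrix plus a normal outgroup, with events mapped to edges by
   Fitch backtrace; the stem carries the truncal events.
4. **Spread classification.** Per metastatic site: earlier/later seeding
   relative to the primary MRCA, monoclonal/polyclonal seeding; per
   patient: monophyletic/polyphyletic dissemination and directed
   intermetastatic edges (source-private subclone with a descendant at a
   second site); per sample class: the index of genomic diversity
   `IGD = Σd/(Σd + l·N)`.

A synthetic-cohort generator with known ground truth (trees, mixtures,
spread labels, noisy measurements) makes the whole pipeline testable
without any external data.

## A worked example

```r
library(clonetrace)

pt <- simulate_patient(sim_config(), seed = 42, n_met_sites = 2)
tr <- trace_patient(pt$segments, pt$metadata, pt$variants, pt$bed)
tr
```

```
<patient_trace P01> 8 samples, 33 events, 7 subclones
<spread_report P01> 2 metastatic site(s)
 site timing n_lineages  clonality
   M1  later          1 monoclonal
   M2  later          1 monoclonal
  phyletic: monophyletic; earlier: FALSE; later: TRUE; polyclonal: FALSE
  intermetastatic: M1 -> M2
```

Both metastatic sites were seeded by single lineages (monoclonal) that
diverged below the primary tumor's MRCA (later spread), all metastases
descend from one branch (monophyletic), and a subclone private to site M1
has a descendant detected at M2 — evidence of spread between the
metastases. The reconstructed clone tree shows the history at
subclone resolution:

```r
tr$tree
```

```
<clone_tree> 7 subclones, 8 nodes, 33 events, parsimony score 33
  stem length 4 (normal -> SC1)
 normal
\-SC1 (4)  [P1]
  +-SC3 (5)  [P4]
  +-SC5 (6)  [P2]
  \-SC7 (4)  [P3]
    \-SC2 (5)  [M1_1,M1_3]
      +-SC4 (3)  [M1_1,M1_2]
      \-SC6 (6)  [M2_1]
```

Edge numbers are event counts (branch lengths); brackets list the samples
where each subclone is detected. `newick(tr$tree)` serializes the tree
with per-edge event lists, `plot(tr$tree)` draws it, and
`run_pipeline()` performs the same analysis cohort-wide from
tab-delimited files, writing per-patient segment tables, event matrices,
Newick trees and spread-report JSONs plus the cohort presence/absence
grid of spread modes.

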