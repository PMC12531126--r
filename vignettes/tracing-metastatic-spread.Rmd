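---
title: "Tracing metastatic spread from multiregional clone fractions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing metastatic spread from multiregional clone fractions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

`clonetrace` reconstructs where and when tumor subclones spread in
patients whose primary tumor and metastases were sampled in several
anatomical locations. The intended data are whole-genome SNP-array copy
number profiles (possibly complemented by targeted deep sequencing of a
gene panel) from formalin-fixed material — the setting of multiregional
studies of pediatric solid tumors, where point mutations are scarce and
large chromosomal alterations carry most of the phylogenetic signal.

This vignette explains the model behind each stage, the tunable
parameters, the design choices made where the problem was genuinely open,
and what the synthetic-data generator does and does not emulate.

## From array signal to clone fractions

Every genetic alteration in every sample is summarized by its **mutated
sample fraction** (MSF), the proportion of all cells carrying it, and its
**mutated clone fraction** (MCF), the proportion of *tumor* cells carrying
it. For a copy-number alteration with `Nt` copies in the altered cells on
a background of ploidy `Np` (the ploidy the log2 ratio was normalized
against; 4 after a whole-genome doubling), the observed mean copy number
is a linear mixture, so

$$\mathrm{MSF} = \frac{N_p\,2^{\mathrm{log2R}} - N_p}{N_t - N_p}.$$

Copy-number-neutral imbalances leave no log2R footprint; their clone size
comes from the mirrored B-allele frequency. With altered cells of allelic
composition $(N_A, N_B)$, $N_B > N_A$, mixed into a diploid heterozygous
normal compartment,

$$\mathrm{MSF} = \frac{1 - 2\,\mathrm{mBAF}}
  {\mathrm{mBAF}\,(N_A + N_B - 2) - N_B + 1}.$$

The "−2" and "+1" terms encode the diploid normal compartment (one B
allele of two); the formula is validated by its limits (mBAF = 1 gives
MSF = 1, mBAF = 0.5 gives 0). Note this means the equation is only exact
when the non-altered compartment is diploid at the locus.

Sample purity (**TCF**, tumor cell fraction) is the mean MSF of the
clearly clonal alterations; `MCF = MSF / TCF`, and alterations whose MCF
falls inside the interval $(\mathrm{TCF} \pm 2\,SD_{\mathrm{MSF}})/\mathrm{TCF}$
— an interval in MCF space centered on 1 — are called clonal and set to
MCF 1. When no anchors are designated, `quantify_sample()` reads the
highest single-linkage cluster of raw MSFs (gap > 0.1) as the clonal
plateau, skipping isolated top values, which under noise are upper-tail
outliers rather than the plateau; a pair is accepted only when its two
values coincide exactly.

Targeted-sequencing variants pass a quality filter (tumor VAF ≥ 0.05,
normal VAF ≤ 0.05, depth ≥ 20 in both, mapping quality ≥ 50) and a
multi-caller consensus rule (two callers in one sample, or two samples
and two callers overall, inside the targeted regions). VAFs convert to
MCFs through the local copy-number mixture; in the diploid limit
`MCF = 2·VAF/TCF`. The allele multiplicity `m` starts at 1 and is raised
to 2 when the raw MCF exceeds 1.1 (`mcf_from_vaf()`). In the pipeline
wrapper this escalation is guarded by a clonality check first: a raw
value inside the clonal interval, extended up to 1.4, is a clonal
heterozygous variant whose raw MCF was inflated by purity
underestimation — a genuinely biallelic clonal variant sits near 2, not
1.2. Without this guard, a few percent purity error halves the MCF of
truncal variants and corrupts downstream clustering.

## Measurement errors are first-class

At realistic FFPE noise (segment log2R scatter around 0.1), a single
event's MCF carries an error between roughly 0.05 and 0.35 depending on
its type: a one-copy loss pins the log2 ratio hard, a high-level gain
barely moves it. Treating all events as equally reliable is what breaks
naive clustering. The pipeline therefore propagates a per-row error:

* array rows get the anchor spread `sd_msf` as a baseline, recalibrated
  patient-wide from the residuals of clonal segments (whose expected
  signal is fixed by the purity) through each row's inversion
  derivative; the pooled residual sd is divided by 0.88 because clonal
  calls are interval-truncated at about ±2 sd;
* variant rows get binomial counting noise plus a purity-uncertainty
  term proportional to the MCF (a deep-coverage VAF is precise, but the
  MCF it implies scales with 1/TCF);
* clonal-pinned values keep their sample's error — the pinning is a
  classification, not a certainty.

Zero-noise data yield zero estimated errors, so every tolerance below
collapses to its nominal value and the pipeline becomes exact.

## Subclonal deconvolution

Alterations acquired on the same branch of the clone tree share one MCF
profile across samples, because an event's MCF is the summed fraction of
all subclones descending through its branch. `reconcile_subclones()`
exploits this:

1. **Profile clustering.** Average-linkage agglomeration; two clusters
   merge while their mean profiles are statistically compatible over the
   whole profile (a regularized chi-square per informative sample, with
   regularizer `mcf_tolerance/2`). Single noisy events cannot be
   assigned per sample, but a genuine branch difference shows up in
   several samples at once and vetoes the merge, while pure scatter
   averages out. A second pass recalibrates the claimed errors against
   the within-cluster scatter actually observed, and a k-means-style
   reassignment undoes early agglomeration mistakes.
2. **Nesting.** Clusters are stacked into a rooted forest under two
   constraints: a child's profile may not exceed its parent's anywhere
   (within the error band), and the identity fractions of a parent's
   children may not exceed the parent's own fraction (the pigeonhole
   rule — two clusters whose fractions sum above the tumor compartment
   cannot be disjoint). Among consistent parents the deepest is chosen;
   parents dominating within the plain tolerance are preferred over
   those valid only through the error slack, because an apparent
   dominance violation is weak evidence for disjointness. This
   deliberately defaults *nested* where both readings are consistent:
   in multiregional data each detectable subclone dominates some sample,
   which makes false nesting essentially impossible (the would-be parent
   is near zero in the child's home sample) while a disjoint default
   systematically breaks true chains.
3. **Cleanup.** Clusters indistinguishable from an already placed one,
   or placeable nowhere without violating capacity, are absorbed as
   noise-split fragments of an existing branch; undetected pass-through
   clusters with a single child collapse into that child; profiles that
   still double-count cells are clipped top-down at the available
   capacity.

Subclones are the cumulative event sets along each chain. Identity
fractions (`fractions`) are the parent-minus-children residuals — the
bookkeeping that makes subclone fractions add back up to event MCFs —
while presence calls (`detected`) additionally require the residual to be
statistically distinguishable from zero: persisting ancestral cells are
only claimed on evidence. Under heavy noise these two views can disagree
for individual outlier measurements; the consensus is then usually closer
to the true clone fraction than the measurement is, which is the point of
pooling events.

`deconvolve_sample()` exposes the classical single-sample view (MCF
clustering plus pigeonhole stacking) in which nested-versus-disjoint
ambiguities are reported disjoint with a flag; the cross-sample
reconciliation above supersedes it whenever more than one sample exists.

## Maximum-parsimony clone trees

The binary subclone × event matrix, augmented with an all-zero normal
outgroup, is scored by Fitch small parsimony. Up to `exhaustive_limit`
(default 9) distinct subclones the minimum-score tree is found exactly by
branch and bound over all unrooted topologies (in C++); beyond that,
greedy stepwise addition with first-improvement
nearest-neighbor-interchange refinement — both deterministic, so a fixed
input always yields an identical Newick string. Ties are broken by fewer
internal nodes after collapsing zero-change edges, then by the
lexicographically smallest clade partition. Events map to edges by the
Fitch backtrace with ambiguities resolved toward the ancestral state, so
homoplasy-free characters map to exactly one gain edge; zero-change edges
collapse, turning ancestral subclones into internal nodes. The edge from
the normal root to the tumor MRCA is the stem, carrying the truncal
events.

Unordered binary Fitch is used as the cost model; no bootstrap, no
likelihood search, and no multi-state copy-number distances — the event
matrix already encodes each alteration as a single acquisition.

## Classifying the spread pattern

With the tree annotated by per-sample detections and anatomical sites:

* **Seeding lineages** of a site are the maximal site-detected subtrees
  whose parent is not detected there; one lineage means monoclonal,
  several polyclonal seeding.
* **Timing**: a lineage whose divergence from the primary-detected part
  of the tree lies strictly above the primary tumor's MRCA seeded
  *earlier* (before the MRCA emerged); at or below it, *later* — a
  lineage attaching exactly at the MRCA counts as later.
* **Phyletic pattern**: monophyletic when all lineage attachment points
  across metastatic sites lie on a single root-to-leaf path.
* **Intermetastatic spread**: a directed edge A → B requires a subclone
  detected at metastatic site A, never in the primary, with a descendant
  (or itself) detected at B; when the only evidence is a subclone shared
  by both sites with no source-private ancestor, both orientations are
  reported unresolved rather than guessed.
* The **index of genomic diversity** for a set of subclones is
  $\mathrm{IGD} = \sum d / (\sum d + l N)$ with $d$ the edge-length
  distances from the set's closest common node, $l$ the stem length and
  $N$ the set size: 0 when all subclones sit at their common node, near
  1 when diversification dwarfs the truncal history.

"Detected at a site" means an identity fraction of at least 0.05 in some
sample of that site — the same threshold as event presence. Relapse
samples count as metastatic sites when anatomically distinct from the
primary (`include_relapse`). Cohort-level contrasts use the two-sided
Mann–Whitney U test for independent groups and a paired t test for
per-patient IGD contrasts, with significance at p < 0.05.

## Key parameters

| parameter            | default | units    | role |
|----------------------|---------|----------|------|
| `mcf_tolerance`      | 0.1     | MCF      | minimum profile-agreement band in clustering and nesting; FFPE arrays do not support finer resolution |
| `detection`          | 0.05    | fraction | event presence and subclone detection threshold |
| `reciprocal_overlap` | 0.9     | fraction | CNAs of one kind merging into one event |
| `exhaustive_limit`   | 9       | subclones| exact parsimony search bound |
| VAF/DP/mapq filters  | 0.05 / 0.05 / 20 / 50 | — | variant quality rules |

## The synthetic cohort generator

`simulate_patient()`/`simulate_cohort()` build patients with known ground
truth so every stage can be validated end to end. The defaults describe
the study conditions this package targets: 17 patients, a median of about
eight samples each, nine patients with metastases in at least two
anatomical sites, and spread-mode target rates equal to the cohort rates
the method aims to resolve (earlier 11/17, later 9/17, polyclonal 3/17,
polyphyletic 6/17, intermetastatic in 8/9 of evaluable patients); purity
0.6–0.95, sequencing depth 1000×, segment log2R noise sd 0.1, mBAF Beta
precision 250, 3–6 events per branch with 80% CNAs, and four synthetic
callers with 15% dropout.

The generator works forward through the same mixture models the pipeline
inverts: a rooted subclone tree is grown with explicit roles (an earlier
lineage diverges above the primary MRCA; polyclonal sites receive two
incomparable lineages; intermetastatic spread is a metastasis-private
subclone whose descendant colonizes a second site), each branch receives
CNA footprints ≥ 30 kb on hg38-sized chromosomes or SNVs inside a
synthetic 300-region panel, per-sample mixtures are drawn with every
subclone dominant in at least one "home" sample, and measurements are
emitted with Gaussian log2R noise, Beta mBAF noise and binomial read
counts. Ground-truth labels are whatever the classifier reports on the
true tree and true detections, which is consistent by construction.

Two aspects are idealized, and they bound what passing tests show about
real data. First, mixtures are rejection-sampled until every pair of
branches is distinguishable (profile separation beyond three tolerances
somewhere, in both directions for incomparable branches): this emulates
the regionally segregated, identifiable clones that manual curation of
real multiregional data presupposes, and the recovery guarantees do not
extend to cohorts with strongly intermixed clones. Second, noise is
generic — there is no FFPE deamination spectrum, no wavy-array artifact,
no segmentation error (segments are taken as given, as the pipeline
starts from segment tables), and recurrent CNAs recur with identical
breakpoints. Absences are emitted as absent, mirroring the careful
manual verification of absence in curated segment files.

## Numerical choices and degenerate inputs

Raw MSFs outside [−0.02, 1.05] raise a QC warning before clamping into
[0, 1]; `Nt = Np` is rejected toward the mBAF path; a zero mBAF
denominator is a degeneracy error. An empty anchor set is an error — the
caller must designate anchors or supply the purity. IGD with a zero stem
and zero distances is undefined and returned as 0 with a warning. Ties
everywhere (cluster order, parent choice, tree enumeration) are broken by
fixed deterministic orderings, so identical inputs give byte-identical
outputs, including Newick strings. Per-patient simulation seeds derive
from the master seed and the patient's index, so permuting a cohort
leaves every patient's data unchanged.

Problem sizes used by the validation suite are chosen to keep a full run
comfortably interactive: exact-parsimony checks use up to 7 subclones and
14 events against exhaustive enumeration, deconvolution recovery uses 50
noise-free patients, and label recovery uses 100 noisy plus 25 noise-free
patients.

## Known limitations

* The mBAF inversion assumes a diploid normal compartment at the locus;
  compositions against a tetraploid background do not invert through it.
* Whole-genome doubling is handled only through the per-segment `Np`
  input; the package never infers WGD.
* Under heavy measurement noise the per-event conservation between
  subclone fractions and individual measured MCFs can exceed twice the
  tolerance for outlier measurements — consensus clustering trades
  fidelity to corrupted single measurements for accuracy of the
  reconstructed clone structure.
* Direction of intermetastatic spread requires a source-private
  ancestor; shared subclones yield unresolved edges, never guessed
  directions.
* The spread taxonomy needs at least one primary-class sample; timing is
  not evaluable without one, and intermetastatic spread needs two
  distinct non-primary sites.

## A minimal worked example

```{r example, eval = FALSE}
library(clonetrace)

pt <- simulate_patient(sim_config(), seed = 42, n_met_sites = 2)
tr <- trace_patient(pt$segments, pt$metadata, pt$variants, pt$bed)
tr$report
plot(tr$tree)

# cohort view
co <- simulate_cohort(sim_config(), seed = 1)
seg <- do.call(rbind, lapply(co$patients, function(p) p$segments))
meta <- do.call(rbind, lapply(co$patients, function(p) p$metadata))
ct <- trace_cohort(seg, meta)
ct$grid
summary(ct)
```
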