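---
title: "Methods: Mediator interactome filtering and super-enhancer analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Mediator interactome filtering and super-enhancer analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mediascape)
```

This vignette documents the models and procedures the package implements,
the parameters that matter, what the synthetic generators emulate (and do
not), and the numerical and design choices behind the code. It states no
empirical result beyond what the test suite and `scripts/acceptance.R`
themselves compute.

## Coordinate and format conventions

All genomic coordinates are 0-based, half-open (BED convention); a TSS is a
single 0-based base; peak summits are absolute 0-based positions. These
conventions are fixed once in the `read_*`/`write_*` functions and every
module consumes their output, so boundary semantics (e.g. "abutting
intervals do not overlap") are decided in exactly one place. Missing
numeric cells in AP-MS tables mean "not detected" and are read as 0;
missing expression replicates stay `NA` and are handled downstream.
Interval machinery (overlap queries, gap-based merging) is delegated to
GenomicRanges/IRanges; the package's own contribution is the rule logic on
top.

## The interactor filter

An AP-MS row carries Mascot and emPAI scores for six purifications: four
Mediator pulls (`untreated`, `benzonase`, `etbr`, `benzonase_rep2`) and one
control per experiment (`control_exp1` pairing with the first three,
`control_exp2` with the replicate). The emPAI score estimates molar protein
abundance; Mascot scores identification confidence. A protein is called an
interactor when, in *every* Mediator purification against its paired
control: Mascot ≥ 50, emPAI enrichment ≥ 5-fold, Mascot enrichment ≥
3-fold, and the protein is not annotated cytoskeletal/cytoplasmic; and,
across treatments, its emPAI is not two-fold lower or more under Benzonase
or EtBr than untreated; and it is present (emPAI > 0) in all four Mediator
purifications.

Zero-handling is the one place the rules need interpretation, and the
package resolves it in favour of absence-of-evidence: a control value of 0
with a positive sample value passes the enrichment ratios (infinite
enrichment), and an untreated emPAI of 0 passes the treatment rule (no drop
is definable) — the presence-in-all-four rule still gates such proteins.
Conversely a treated value of 0 against a positive untreated value is a
complete drop and fails. Annotation-driven removals (cytoplasmic proteins,
core subunits, known-interactor novelty) are input id lists, not live
database queries, to keep runs deterministic and offline.

Edge thickness for network export bins the mean emPAI over the four
Mediator purifications at breakpoints 0.25 / 0.75 / 1.5. The value 0.25
itself goes to the thinnest bin: the published category text leaves the
point unassigned and assigning boundary values downward keeps the bins
half-open in a consistent direction.

Every failing protein carries machine-readable reasons
(`mascot_min:<role>`, `empai_fold:<role>`, `treatment_drop:benzonase`, …),
which the tests use to verify that each planted decoy class fails for the
planted reason rather than incidentally.

## Enhancers and the hockey-stick cutoff

Enhancers are Ep300 peaks with ≥ 1 bp H3K27ac overlap; the enhancer
footprint is the Ep300 peak interval (Ep300 marks the punctate element; the
acetylation domain is broader). Constituents overlapping ±1 kb of any TSS
are removed *before* stitching, so promoter signal never counts toward a
stitched enhancer. Stitching merges constituents whose inner gap is ≤ 12.5
kb (transitive closure per chromosome, implemented with
`GenomicRanges::reduce`, cross-checked in tests against a union-find
oracle). Each stitched region is ranked by its total Med1 signal summed
from a dense coverage track; background subtraction is available but off by
default, since the ranking axis is total reads.

The SE cutoff is geometric. With regions sorted by signal ascending, rank
scaled to [0, 1] by `i/(n-1)` and signal scaled by its range, the cutoff
index is the first position whose discrete forward slope exceeds 1; regions
with signal strictly above the signal at that index are super enhancers.
This is the tangent-slope-1 definition of the hockey-stick plot, it is
deterministic, invariant to positive rescaling of the signal, and on the
analytic curve \(y_i = (i/100)^2\) (where the derivative equals 1 exactly at
scaled rank 0.5) it labels precisely the upper 50 of 101 regions. Ties at
the cutoff signal go to "typical". All-equal signals are degenerate: zero
SEs with a warning. Ranking is genome-wide, not per chromosome.

A structural caveat worth stating: on the scaled curve the *average*
discrete slope is exactly 1, so for any continuous, light-tailed signal
distribution some early slope exceeds 1 and the rule will call a
non-trivial SE fraction even in the absence of planted clusters. The
cutoff is meaningful for the strongly right-skewed, elbow-shaped curves
real Mediator signal produces (and that the fixture generator emulates),
not as a null-calibrated detector on smooth curves. Tests therefore assert
recovery of planted clusters and the caller's invariants, not a false-SE
rate on structureless signal.

## Colocalization and site categories

Factor comparisons use the top 5000 sites by significance score (ties at
the boundary broken by coordinate; fewer peaks are kept with a warning).
Two sites overlap when their summits are within 200 bp, inclusive, on the
same chromosome; the implementation is a sorted `findInterval` sweep with
the quadratic all-pairs scan kept as a test oracle. Site categories (TSS /
SE / typical enhancer / other) are decided by summit position with TSS
priority, matching the way "non-TSS" subsets are formed after promoter
removal; the promoter half-width defaults to 1.5 kb and is exposed as a
flag (1 kb being the other definition in circulation). In per-category
overlap matrices only the query factor is restricted to the category; the
subject factor stays its full top-N set, keeping the denominator semantics
("share of A's category-c peaks near any B peak") simple.

## Gene categories

A gene's promoter-domain width is the widest H3K4me3 domain covering the
TSS base itself (configurable in principle to a window, but domain-covers-
TSS is the simplest deterministic reading). Broad genes are the top 5% of
nonzero widths, threshold at the 95th percentile with ties included, so the
count is ⌈0.05·n⌉ up to ties. Active genes have mean RPKM strictly above
0.5. Enhancer-to-gene assignment takes the nearest active TSS by edge
distance (0 inside the region; ties lexicographic by gene id;
never across chromosomes). SE genes are nearest genes of SEs (a gene may
own several SEs); typical genes exclude SE genes. Crossing SE status with
broadness yields the four categories; active genes in none of them are
`none`. The Top-100 subsets walk SEs by descending Med1 signal collecting
each SE's nearest gene once (at its highest SE), split by broad status;
Broad−SE takes the 100 widest domains among broad genes with no SE.

## Metaprofiles and knockdown response

TSS metaprofiles use 10 bp bins over ±12 kb. Minus-strand windows are
reversed so positive offsets always point into the gene body; the reversed
window is shifted by one base so the TSS base occupies the same profile
index on both strands, which makes mirror symmetry exact (mirroring the
genome and flipping all strands reproduces the profile bit for bit, a
property the tests assert). Windows clipped at chromosome edges contribute
their covered bases only, and each base is renormalized by the number of
regions covering it rather than dropping the gene. Units are signal per bp
per region, scaled by `1e7 / total_tags`.

Knockdown summaries restrict mean log2 fold change and its SEM to genes
with a significant call (the caller supplies the significance flag; the
package does not re-derive it), while the fraction downregulated divides
significant-and-negative genes by all DE-measured genes of the category —
the convention that makes "all significant at −1" give 1.0 and "nothing
significant" give 0. Group comparisons use two-sided pooled-variance
Student t-tests (`stats::t.test(var.equal = TRUE)`; Welch via a flag), with
a closed-form guard returning p = 1 (equal means) or 0 for doubly-constant
groups, where the generic test is undefined.

## What the generators emulate

`gen_apms_dataset` plants four protein classes: true interactors and core
subunits (log-normal emPAI, present in all four Mediator samples, absent
from controls, treated/untreated ratios confined to [0.8, 1.3]),
chromatin-dependent binders (treated emPAI divided by at least the drop
factor, default 3), contaminants (control abundance comparable to sample,
sometimes absent from Mediator samples), and a few cytoplasmic-flagged
proteins that would otherwise pass. Mascot scores are scaled from emPAI
with a floor for detected proteins of the specific classes. Class
separations are wide by design: at the defaults the filter's precision and
recall on the planted set are 1 at any seed, which is what makes the
planted-recovery tests sharp rather than statistical. Defaults are
50 true / 10 chromatin-dependent / 40 contaminant / 26 core / 5
cytoplasmic; an endogenous-IP id list containing 60% of the true
interactors plus the core subunits accompanies the table for
overlap-validation runs.

`gen_genome_fixture` lays one gene per tile on two chromosomes (~2.2 Mb
each at the defaults: 200 genes, 15 SE clusters of 3–4 constituents, 75
typical-enhancer genes of which some have split constituents that must
stitch back together, 10 broad genes, 90 active genes with no enhancer, 30
inactive). Tiles keep ≥ 16 kb between features of neighbouring genes so
nothing stitches across. SE constituents get ~10× the per-bp Med1
intensity of typical constituents, and typical totals are drawn from a
tight band so the ranked curve has a single sharp elbow — the planted
clusters are then recovered deterministically, which is what the 20-seed
sensitivity/precision check in the acceptance script measures. Broad-gene
counts are planted to coincide with the top-5% width slice at the default
gene count. Decoy Ep300 peaks without H3K27ac and promoter-proximal
enhancer peaks exercise the definition and TSS-exclusion filters. Summits
carry truncated Gaussian jitter (sd 20 bp, capped at ±60 bp) to exercise
the 200 bp window without ever leaving it; non-colocalizing factor peaks go
to feature-free zones > 1 kb from any planted summit.

Knockdown flags are planted by *stratified assignment*: per category,
exactly `round(sig_frac·n)` genes are significant and `round(p·n)` of them
downregulated, membership randomized. Realized down-fractions therefore
equal planted probabilities up to rounding at every seed, which turns the
±0.05 recovery check into a deterministic property instead of a coin flip.
Expression is log-normal with category-ordered means (SE+Broad highest).

What the fixtures do **not** emulate: read-level noise (coverage is
piecewise-constant intensity, not sampled reads), mappability and
GC artefacts, overlapping genes and alternative TSSs, heavy-tailed typical
enhancer signal, peak-caller false positives, and spectral-level AP-MS
noise. Passing tests on these fixtures demonstrates the correctness of the
rule chain and its boundary behaviour, not robustness to those real-data
phenomena.

## Problem sizes and reproducibility

Test and acceptance runs use the generator defaults above (131 proteins;
~200 genes, ~150 constituent peaks and ~80 stitched regions per genome
fixture; 20 fixture seeds for the SE-recovery rates; 400 genes per category
for the knockdown check), sizes chosen so the full suite completes in well
under a minute while every count being asserted is still structurally
non-trivial. All randomness flows through a single seed argument per
generator call; generators restore the caller's RNG state, and rerunning
any stage with identical inputs and parameters is bit-reproducible. The
pipeline functions (`pipeline_config()`, `run_pipeline()` and the stage
runners) are the orchestration surface; parameters and input checksums are
echoed into a JSON manifest so a run can be audited after the fact. A
shell entry point would add nothing over `Rscript` one-liners on these
functions, so the package ships functions plus `scripts/acceptance.R`
rather than a separate CLI binary.

## Known limitations

* The tangent cutoff is the standard geometric definition; the original
  ranking script it mirrors is not archived with an exact release, so small
  count differences against historical SE lists are possible.
* The published broad-promoter list the analyses reused was taken from
  earlier work rather than recomputed; the top-5% rule here may differ at
  the margin in membership.
* Whether enrichment criteria should use per-experiment controls or the
  maximum over both controls is not fully specified upstream;
  per-experiment pairing is implemented (and is the stricter reading for
  the replicate experiment).
* `read_signal_bedgraph` materializes dense per-chromosome coverage;
  fine for the fixture scale and single mammalian chromosomes, but a whole
  mammalian genome at 1 bp resolution would need a run-length or bigWig
  representation, which is out of scope here.
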