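---
title: "Comparative gene retention analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative gene retention analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panretain)
```

## The scientific problem

Most of what is known about gene retention after duplication comes from
cataloguing duplicates in single reference genomes, which mostly reflects
ancient events. A pangenome changes the picture: when tens of resequenced
lines of a species are available, a gene duplicate that is *partially*
retained across lines is a duplicate caught mid-fixation, and the fraction
of lines that carry it is a direct, population-level readout of the
selective forces acting on it.

`panretain` implements this comparative analysis for panels of related
species that differ in ploidy (the motivating design is barley at 2x,
wild emmer at 4x, and bread wheat at 6x). Its stages are:

1. **Retention rates.** For each hierarchical orthologous group (HOG) and
   species, the gene retention rate is
   `GRR = 100 * n_present / n_lines` over the species' pangenome lines.
   A line counts as carrying the HOG if any member gene for that species
   is present. GRR is kept at full rational precision internally and only
   rounded for reports.
2. **Dosage-pattern filter.** HOGs whose GRR decreases strictly along the
   ploidy series (diploid > tetraploid > hexaploid) carry the signature
   of a dosage constraint: the more redundant homolog sets a genome has,
   the weaker the constraint on each copy and the likelier the loss. Ties
   fail the default strict filter; a relaxed mode (`strict = FALSE`)
   accepts ties as long as one step is strict.
3. **Preference categories.** For a two-species comparison the ratio
   `R_bw = GRR_barley / GRR_wheat` is binned at the cutoffs `>= 1.2`
   (barley-preferential), `0.9 < R < 1.1` (neutral), and `<= 0.8`
   (wheat-preferential). The cutoffs deliberately leave the gaps
   `(0.8, 0.9]` and `[1.1, 1.2)`; rather than silently merging them into
   a neighbouring class we label them `unassigned` and exclude them from
   enrichment. A gene fully lost in wheat but retained in barley has
   `R = +Inf` and is classified barley-preferential (the extreme case);
   a gene absent from both panels is `undefined` and excluded.
4. **Family-size correlation.** Family size is the number of HOGs under a
   parent orthogroup (OG); for each OG we average member-HOG GRRs
   (unweighted) and report the Pearson correlation and least-squares
   slope of mean GRR against family size, per species.
5. **Duplication typing, Ka/Ks, codon selection tests, GO enrichment** on
   the genes selected by the filter (sections below).

## Input model and conventions

HOG tables are tab-separated with columns `HOG`, `OG`,
`Gene Tree Parent Clade`, then one gene-list column per species
(`", "`-separated with a bare-comma fallback; empty cells mean the group
is absent from that species' annotation, which is exactly the situation
of a gene missing from a reference genome). Presence/absence matrices are
lines x genes with `0/1` or `absent/present` cells. Gene coordinates come
from GFF3 `gene` records; each gene gets a 0-based rank along its
chromosome ordered by start with ties broken on gene id, so ranks are
deterministic. Newick trees may label foreground branches with the `#k`
suffix convention on the subtending node or tip.

Presence can also be inferred from pre-tabulated SNP genotype
missingness: a gene is called absent in a line when more than
`max_missing_fraction` (default 0.8) of its genotyped SNPs are missing.
No standard cutoff exists for this step, so the default is exposed as
configuration; the call is monotone in the threshold by construction.
Lines with no genotyped SNPs are flagged "no-data" (`NA`). By default
no-data counts as absent — matching how unassembled regions are usually
counted — and `exclude_nodata = TRUE` removes such lines from GRR
denominators instead.

## Duplication classification

Homology hits are filtered at `E <= 1e-5`, keeping the top 5 non-self
hits per query (ties broken by bit score, then subject id). Collinear
blocks are maximal chains of anchor pairs, strictly monotone in both
genomes' ranks (increasing or decreasing in the second genome for same
vs inverted orientation), with consecutive anchors at most 25 ranks apart
on both sides; chain length is the score, the best chain is extracted
first, each anchor belongs to at most one block, and chains shorter than
5 anchors are dropped. We deliberately use chain length rather than an
E-value-weighted score: it is simpler, fully reproducible, and equals an
exhaustive best-chain search on every instance the test suite throws at
it.

Every gene is then assigned exactly one class with precedence
`WGD/segmental > tandem > proximal > dispersed`, and `singleton` when it
has no retained hit: block anchors are WGD/segmental; a partner at
adjacent rank on the same chromosome is tandem; within the 10-gene
proximal window is proximal; everything else is dispersed. The precedence
order and window size are stated here because classifier conventions
differ between tools; both are configurable. Hits are symmetrized first,
so classification never depends on hit direction.

## Ka/Ks by NG86 counting

The pairwise estimator is Nei–Gojobori (1986) counting. Per codon, each
position contributes one site split by the fraction of its possible
single-nucleotide changes that are synonymous, with changes producing
stop codons removed from the possibility set (variants of NG86 differ
here; this convention is asserted against an independent enumeration
oracle). Codon pairs differing at k positions average their synonymous /
nonsynonymous difference counts over all k! mutational pathways,
discarding pathways through stops. Proportions `pS = Sd/S`, `pN = Nd/N`
are Jukes–Cantor corrected, `d = -3/4 log(1 - 4/3 p)`; `p >= 3/4` is
reported as saturated (`NA`). `omega = Ka/Ks` is `NA` when `Ks = 0`
(optionally `Inf` when `Ka > 0`). The estimator is symmetric in sequence
order and satisfies `S + N = 3 x` compared codons exactly.

Back-translation maps a protein alignment onto codon space (gap `-` to
`---`), verifying that each ungapped protein translates exactly from its
CDS; a trailing stop codon on the CDS is tolerated and dropped.

## Codon substitution models

The likelihood machinery is a GY94-style model: off-diagonal rates for
single-nucleotide codon changes are
`pi_j * kappa^[transition] * omega^[nonsynonymous]`, zero for
multi-nucleotide changes. Equilibrium frequencies default to F1X4
(nucleotide frequencies pooled over the three codon positions, stops
removed, renormalized). Likelihoods are computed by Felsenstein pruning
with per-edge transition matrices from the symmetric eigendecomposition
of the reversible generator; pattern compression and an
underflow-triggered rescaling pass keep it fast and safe. Branch lengths
are *fixed from the input tree* rather than jointly optimized — the
package's selection tests are about omega, and fixing lengths keeps every
fit inside a small, well-conditioned parameter space.

**Rate normalization.** For branch models each Q is scaled so the
expected substitution rate at equilibrium is 1; branch lengths are then
expected substitutions per codon under that branch's omega. For
branch-site mixtures this per-matrix convention would be wrong in an
important way: it would give a positively selected site class the same
total substitution rate as a conserved class, erasing the rate signature
of selection and leaving the likelihood nearly flat in `omega2`. Mixture
models therefore scale all class matrices by the one *neutral*
(`omega = 1`) rate factor, so classes evolve at their relative rates and
branch lengths read as neutral-scale substitutions per codon. The
simulator uses the same conventions as the estimators throughout.

**Branch models** share one kappa and give each branch-label group its
own omega (one-ratio, two-ratio, ..., n-ratio). **Model A** mixes four
site classes — conserved (`omega0 <= 1`), neutral (`omega1 = 1`), and
two classes whose background is conserved/neutral while foreground
branches get `omega2 >= 1` — with proportions constrained by
`p2a/p2b = p0/p1`. Its null fixes `omega2 = 1` (1 df). Reported `np`
counts the free selection parameters (1, 2, ..., and 4 vs 3 for Model A
vs null), excluding kappa and the fixed branch lengths, matching the
usual presentation of such model tables.

Optimization is bounded quasi-Newton (`L-BFGS-B`) on log/logit-transformed
parameters, `omega` in `[1e-4, 50]`, `kappa` in `[0.1, 20]`, with 5
seed-controlled random restarts by default. Model A profiles the class
proportions: for fixed `(kappa, omega0, omega2)` the per-class site
likelihood matrix is cached and the proportions are optimized in a cheap
inner step, so the expensive pruning passes scale with the outer
parameters only. Degenerate inputs (no variation) leave omega
unidentifiable; fits then return `converged = FALSE`.

**LRTs** use the upper-tail chi-square at the difference in free
parameters; slightly negative statistics from optimizer noise are clamped
to zero with a warning. One caveat is stated rather than hidden: when
data are generated *at* `omega2 = 1`, the truth lies on the boundary of
the alternative's parameter space and the asymptotic null of the Model A
LRT is the mixture `0.5 chi2_0 + 0.5 chi2_1`, making the plain df = 1
test conservative. The test suite checks both readings: the plain test
must not be anticonservative, and under the boundary-corrected reference
the rejection rate must be consistent with the nominal 5%.

Naive empirical Bayes (NEB) site posteriors evaluate class memberships at
the fitted parameters; sites with posterior above 0.6 for the foreground
classes are reported. NEB ignores parameter-estimation uncertainty
(Bayes empirical Bayes is deliberately out of scope), which is one reason
posterior-based site identification has limited power for sites whose
background class is neutral.

## GO over-representation

Enrichment is the exact upper-tail hypergeometric test per term
(`P[X >= k]` for `k` query genes among `K` annotated in a universe of
`N`), with the universe defaulting to all annotated genes. The enrichment
score is `-log10(raw p)`. Multiple testing uses Benjamini–Hochberg FDR:
the workflow this mirrors is often run through a web service's proprietary
stepwise procedure, which is not reimplementable from its description;
BH is a well-defined, widely accepted substitute, and the divergence is
documented here. GO-graph propagation is off by default (annotations are
taken as given). Term-overlap edges (shared-gene counts between term gene
sets) support the enriched-term network view.

## The synthetic study and what it does (not) show

The generators produce every input the pipeline consumes, with ground
truth attached, so the full analysis runs without any external download:

* `gen_pangenome()` mirrors the motivating panel — 20/20/15 lines at
  ploidy 2/4/6 — with family sizes from a truncated geometric
  distribution (success probability 0.5, mean 2, truncated at 12) and
  per-line presence drawn independently with retention probability
  `plogis(beta0 - beta_family (f-1) - beta_ploidy (ploidy/2 - 1))`.
  The logistic form is the minimal monotone dosage model consistent with
  the dosage-constraint hypothesis; the defaults
  (`beta0 = 2.5, beta_family = 0.35, beta_ploidy = 0.9`) put a
  single-copy diploid gene near 92% retention and a size-4 hexaploid
  family member near 41%, spanning the range where partial retention is
  observable in 15–20 lines. An optional family-by-ploidy interaction
  term steepens the family-size slope with ploidy.
* `gen_genome_layout()` plants tandem/proximal/dispersed/segmental events
  at regularly spaced gene ranks, separated by more than the chaining gap
  so distinct events can never merge into one collinear block, and emits
  a hit for every planted pair.
* `evolve_codons()` samples root codons from pi and propagates them with
  the exact transition matrices of the fitted models (never generating
  stop codons), under branch-wise omega or a Model A class mixture.
* `gen_go()` annotates genes at a per-term background rate and
  over-represents one planted term in a designated query set by a stated
  fold.

Because lines are independent Bernoulli draws, the synthetic pangenome
has no population structure, no linkage between neighbouring genes, no
reference-bias in presence calls, and no species-specific selection
beyond the ploidy term — under a pure dosage model essentially no gene
ends up wheat-preferential, whereas real panels show a substantial
minority. Passing tests therefore demonstrate that the statistics,
filters and model fits do what they claim on data generated under their
own assumptions; they do not validate orthology inference, assembly
quality, or the biological model itself.

## Problem sizes and numerical choices

The shipped study and test suite run at deliberately modest sizes chosen
to exercise every code path with stable statistics: 300 orthogroups
(~600 HOGs) for retention analyses; 500-codon alignments on 6–8 taxa for
model fits; 200 replicates of 200 codons on 4 taxa for the LRT size
check; 500 random pairs for the NG86 oracle comparison. Optimizer
tolerances: `factr = 1e8` (about 1e-8 relative) for single fits, relaxed
to `1e9` inside the replicate study where only the LRT statistic at
0.05 resolution matters. Chain detection ties are broken deterministically
(subject id for hits, input order via stable DP for chains), and every
generator is a pure function of its configuration and seed.

## Known limitations

* Branch lengths are taken from the input tree; `omega` estimates absorb
  any misspecification of relative branch lengths.
* NG86 is a counting method: it saturates above `p = 3/4` and
  underestimates high omega; the likelihood machinery is the reference
  for strong selection.
* The Model A `p2a/p2b` split is weakly identified in small alignments;
  only the constrained mixture form is fitted, and summary tables that
  lump `p2 + p3` are mirrored by reporting the same aggregate.
* BH-FDR replaces the original web service's multiple-testing procedure;
  adjusted p-values are not numerically comparable to that service's
  output, though rankings typically agree.
* The orthology table is consumed, never inferred; garbage in, garbage
  out applies to HOG quality.
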