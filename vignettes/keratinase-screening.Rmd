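---
title: "Screening annotated proteomes for candidate keratinases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening annotated proteomes for candidate keratinases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Keratin is a densely cross-linked structural protein that resists the
common proteolytic enzymes; the proteases that do degrade it
(keratinases, EC 3.4.21/24/99.11) are biotechnologically valuable but
hard to recognize from sequence alone. Single purified enzymes never
fully solubilize native keratin, so the working hypothesis is that a
*pool* of secreted proteases acts together. `keratinscreen` operationalizes
that hypothesis as a genome-scale screen: given the annotated proteomes
of a few related strains with *different* keratinolytic phenotypes, plus
panels of functionally characterized keratinases and of deliberately
non-keratinolytic proteases (trypsins, papains, pepsins), it nominates
the proteins of a focal strain most likely to explain its phenotype.

The screen is a pipeline of seven stages, each an independent,
re-runnable function:

1. **Mining** — proteins whose consolidated annotations (several
   annotators are merged by protein id) contain any of nine protease
   keywords (peptidase, protease, proteinase, sortase, caspase,
   penicillin-binding protein, insulinase, snapalysin, mycosin) are
   flagged as putative proteases. Matching is plain case-insensitive
   substring matching: the keyword list deliberately contains substrings
   of real descriptions ("peptidase" must hit "metallopeptidase"), and
   the one multi-word keyword is matched as a phrase so the bare word
   "protein" never triggers. The original workflow confirmed hits by
   manual homology searching; we replace that unreproducible step with a
   `review_flagged` column marking proteins supported by a single
   annotator only.
2. **Family assignment** — reciprocal best hit against a MEROPS-style
   reference FASTA (`>id|S08` headers) at E-value 1e-20. Ties break by
   bitscore, then reference id, so assignment is deterministic.
3. **p-orthogroups** — connected components of the all-vs-all alignment
   graph thresholded at E-value 1e-40, over the mined proteases only.
   Components of size one are reported as "unassigned p-orthogroup"
   peptidases — in the motivating data these strain-unique proteins are
   themselves candidates of interest. We use transparent
   connected-components clustering rather than a full orthology inference
   tool: the original analysis used such a tool as a black box at the
   same threshold, and the component structure is the testable core; we
   do not claim count parity with any specific tool.
4. **Similarity network** — nodes are the mined proteases plus both
   reference panels; an undirected edge joins two proteins when the
   smaller of the two directed E-values passes the threshold (1e-40 by
   default; 1e-5 to 1e-80 are the supported sweep values). Edge weight
   is `-log10(E)` capped at 300 (E = 0 maps to the cap). The weight
   transform is the standard similarity-network choice; it is
   config-overridable because the upstream description of "weighted"
   does not pin it down. Communities come from weighted Louvain at
   resolution 1, made deterministic by drawing the node order from the
   run seed; restarts from random initial partitions (plus a final
   refinement pass) are kept because pure single-node moves provably get
   stuck on small graphs — the suite checks the result against
   exhaustive maximum modularity on graphs of up to 8 nodes. A query
   protein is **keratinase-linked** when its community contains at least
   one panel keratinase (a direct-edge variant is available; community
   membership is the default because the original account describes
   whole communities as keratinase-related).
5. **Localization embedding** — each protein carries 14 localization
   scores: four compartment scores from a PSORTb-style predictor, four
   from a CELLO-style predictor, and six from SignalP 5 (SP, TAT, LIPO,
   OTHER, plus two derived features). The derived features are not given
   formulas upstream; we define signal-peptide possibility as SP + TAT +
   LIPO and intracellular as 1 − that sum, which makes the SignalP
   block internally consistent and keeps both features in [0, 1]. The
   matrix is z-scored per column (zero-variance columns are dropped with
   a warning), embedded by PCA (eigendecomposition of the correlation
   structure; loadings are eigenvectors scaled by the square root of
   their eigenvalues) and by exact t-SNE (perplexity 30, 1000
   iterations, random Gaussian initialization from the run seed; early
   exaggeration 12x for the first quarter of the iterations, momentum
   0.5 then 0.8, and the auto learning rate max(n/48, 50) — the classic
   fixed rate of 200 catapults points out of their clusters on small
   inputs and fragments them irrecoverably, which is why modern
   implementations adopted the auto rule). Both
   coordinate sets are min-max normalized to the unit square. DBSCAN
   (Euclidean, eps 0.05, min_samples 4 counting the point itself)
   clusters the t-SNE plane into **t-SNE groups**; border points attach
   to their nearest core point so labels are independent of input
   order, and groups are renumbered 0..k−1 by decreasing size. The
   upstream account gives no DBSCAN parameters; eps 0.05 on the unit
   square with min_samples 4 forms groups of the scale reported there
   (tens of points out of ~700) on our fixtures, and both knobs sit in
   the configuration.
6. **Phylogeny per group** — every t-SNE group that contains at least
   one panel keratinase (and at least three members) is analyzed:
   columns with occupancy below 70% are removed from the group MSA
   (occupancy = fraction of sequences with a residue in the column;
   rows left all-gap are dropped with a warning), a tree is taken from
   the inputs if one with the matching tip set was supplied (externally
   inferred ML trees are the intended source) or built by
   neighbor-joining on p-distances as a fixture-grade fallback, and the
   tree is midpoint rooted. Ancestral states over the four categories —
   functional keratinase, keratinase-linked, three-strain, non-keratinase
   — are reconstructed under the equal-rates (ER) Mk model:
   `P_same(t) = 1/k + (k−1)/k·e^(−kqt)`, `P_diff(t) = (1−e^(−kqt))/k`,
   with the single rate q fitted by maximum likelihood (Felsenstein
   pruning, flat root prior — the canonical choice under ER symmetry)
   and node marginals computed exactly by an outside-inside pass. The
   tooling this emulates phrases reconstruction as 1000 stochastic
   character maps; we treat exact marginals as the default because they
   are deterministic, and `method = "simmap"` reproduces the sampling
   mode (seeded; the suite checks the 1000-draw node frequencies stay
   within 0.05 of the exact marginals).
7. **Clade selection** — an internal node is selected when (i) the
   ancestral probability of keratinase + keratinase-linked strictly
   exceeds 50%, (ii) its subtree contains at least one panel keratinase,
   and (iii) at least one focal-strain tip. The probability filter sums
   the two categories by default; whether the original filter summed
   them or tested each alone is ambiguous, so `"either"` is available as
   a configuration switch. Nested selected nodes are subsumed by their
   highest selected ancestor (how nested qualifying clades were reported
   upstream is not stated; maximal-clade subsumption reports each
   candidate once and never drops one). Candidates are the deduplicated
   focal-strain tips of the maximal selected clades.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `family_evalue` | 1e-20 | RBH cutoff for family assignment |
| `orthogroup_evalue` | 1e-40 | component cutoff for p-orthogroups |
| `network_evalue` | 1e-40 | edge cutoff for the similarity network |
| `louvain_resolution` | 1 | modularity resolution |
| `tsne_perplexity` | 30 | t-SNE perplexity (< n; warn if n < 4x) |
| `tsne_iterations` | 1000 | gradient-descent iterations |
| `dbscan_eps` | 0.05 | DBSCAN radius on the unit square |
| `dbscan_min_samples` | 4 | DBSCAN core threshold (self included) |
| `occupancy_threshold` | 0.70 | minimum kept column occupancy |
| `clade_probability_threshold` | 0.5 | strict lower bound, filter 1 |
| `random_seed` | — | drives t-SNE, Louvain order, fixtures |

E-values use the gapped Karlin–Altschul conversion (BLOSUM62, gap open
11 / extend 1, lambda 0.267, K 0.041): bitscore = (lambda·S − ln K)/ln 2,
E = m·n·2^(−bitscore) with n the total residue count of the searched set.
This reproduces blastp-comparable magnitudes — the suite checks that the
built-in engine and a blastp adapter select the same significant pairs on
fixtures — but individual E-values from other aligners can differ by an
order of magnitude, which is why every threshold is a configuration
value rather than a constant.

## What the synthetic scenario emulates — and what it does not

`gen_keratinase_scenario()` builds the world the pipeline expects: three
strains (one focal), a keratinase panel and a non-keratinase panel, and
five planted protein families at 5% within-family divergence over
length-240 sequences (random-background identity between families).
Two extracellular families share members with the keratinase panel (the
planted candidates are exactly their focal-strain members); one
extracellular family has no keratinase (filter-2 decoy); one
keratinase-sharing extracellular family lacks the focal strain
(filter-3 decoy); one family plus all orthogroup singletons are
intracellular. Localization vectors are drawn around four profile
centroids (Sec-, Tat-, lipoprotein-signal exports and cytoplasmic) with
seeded Gaussian noise, written in all three raw predictor dialects and
as the fused table. Sequences are indel-free by default so identity
arithmetic is exact and the planted MSAs are trivially valid; an indel
mode exercises gap handling separately. The `minimal` preset (~66
proteins) sets perplexity 10 and DBSCAN eps 0.08 — the paper-scale
defaults assume ~700 embedded points, and on a plane an order of
magnitude sparser the nearest-neighbour spacing roughly doubles; the
`paper-shaped` preset keeps the standard defaults at the original scale
(580 query proteases + 61 + 50 panel sequences).

A green recovery test therefore establishes that the machinery — mining,
thresholds, community linkage, embedding, the three filters — composes
correctly on data whose truth is known. It does not establish that real
annotation servers, real localization predictors, or real protein
evolution (no site-rate heterogeneity, no selection, no domain shuffling
in the generator) behave like the fixture, and it cannot reproduce
counts that depend on those external tools' internals.

## Numerical choices and degenerate inputs

* Louvain ties in modularity gain break toward the lower community id;
  community and group ids are assigned by decreasing size then smallest
  member id, so all labels are reproducible.
* The ER rate is optimized on log q over [1e-8, 1e3] by golden-section
  search; pruning partials are rescaled per node, so 200-tip trees stay
  in range. Rate recovery is validated at q = 0.5 on 200-tip simulated
  trees (within a factor of 2 in ≥ 90% of seeded replicates).
* Trees with all-zero branch lengths midpoint-root deterministically at
  the first tip, with a warning. Negative NJ branch lengths clamp to 0.
* An empty mined set short-circuits the pipeline into an empty report
  (success, not an error); an embedding with fewer than 5 proteins is
  an error.
* A protein missing from any localization file is an error listing the
  ids — no imputation, since a fabricated compartment score could flip
  the extracellular call.
* t-SNE determinism: same matrix, perplexity, iterations and seed give
  bit-identical coordinates; the global RNG state of the caller is
  saved and restored around every stochastic component.

## Known limitations

* Orthogroups are alignment-graph components, not a full orthology
  inference; paralog splitting within a component is out of scope.
* The built-in aligner is exact Smith–Waterman without heuristic
  seeding or composition-based statistics; for hundreds of sequences
  the blastp adapter is selected automatically when available.
* NJ trees are a fallback for self-contained runs; for real analyses
  supply externally inferred ML trees as Newick.
* The three localization parsers accept one tabular dialect each;
  outputs of other predictor versions need reformatting to the
  documented columns (or the fused 14-column table).
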