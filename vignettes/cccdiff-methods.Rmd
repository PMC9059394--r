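---
title: "Differential cell-cell communication with cccdiff: models and methods"
author: "cccdiff maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential cell-cell communication with cccdiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`cccdiff` infers cell-cell communication (CCC) between annotated cell
populations from log-normalized single-cell or single-nucleus expression and
compares it between two sample groups (for example, disease versus control
brain donors). The pipeline covers: ligand-receptor (L-R) interaction
scoring with heteromeric complexes and cofactors; label-permutation
significance; aggregation to signaling-pathway scores, information flow and
relative information flow; two differential designs (a merged "global"
comparison and a per-sample pseudo-bulk design with Wilcoxon tests and
Benjamini-Hochberg FDR); latent communication patterns by non-negative
matrix factorization (NMF); downstream overrepresentation, gene-list
overlap and preranked gene-set enrichment statistics; and spatial L-R
co-expression checks. A synthetic-data generator with planted ground truth
makes every stage testable without external downloads.

# The communication model

## Per-type expression summaries

For each cell type $t$ and gene $g$ the package computes a summary
expression $E_{t,g}$ and the fraction of cells of $t$ with non-zero
expression. Genes expressed in less than 20% of a type's cells (the
`threshold` parameter) contribute zero expression — they are treated as not
reliably detected in that population.

The default summary is the 25%-truncated mean (`summary = "trimean"`):
values are sorted and the lowest and highest quartiles discarded before
averaging, following base R's `mean(x, trim = 0.25)` convention. The
truncated mean is robust to the zero inflation typical of droplet-based
data; a plain mean is available via `summary = "mean"`. A geometric mean
across individual cells — another summary sometimes named in this context —
would be nulled by any zero-expressing cell and is therefore not offered;
the geometric mean in this package operates across complex subunits (below).
Note one interaction between the two choices: a gene expressed in exactly
20-25% of cells passes the detection filter but still has a zero truncated
mean, because the non-zero values all fall in the discarded upper quartile;
with `summary = "mean"` the same gene contributes a positive value.

## Complexes and the mass-action response

Ligands and receptors may be heteromeric complexes. The complex-level
expression in a cell type is the geometric mean of its subunit summaries,
and the absence of any subunit nulls the complex — a receptor cannot signal
without all of its chains.

The strength ("communication probability") of interaction $i$ from sender
$s$ to receiver $r$ follows a Hill-type mass-action response:

$$ P_{s,r,i} = \frac{L_s R_r'}{K_h + L_s R_r'} \cdot
   \left(1 + \frac{AG_s}{K_h + AG_s}\right)
   \frac{K_h}{K_h + AN_s}, \qquad
   R_r' = R_r \left(1 + \frac{CS_r}{K_h + CS_r}\right)
   \frac{K_h}{K_h + CI_r}. $$

$L_s$ and $R_r$ are the ligand and receptor complex expressions; $AG$, $AN$
are arithmetic means of soluble agonist and antagonist gene summaries in the
sender; $CS$, $CI$ are co-stimulatory and co-inhibitory membrane co-receptor
terms in the receiver. The half-saturation constant defaults to
$K_h = 0.5$ on the summarized log-expression scale, the value used by the
mass-action formulation this model follows; it is exposed as `kh` in
`cccParams()`. Without cofactors the strength lies in $[0, 1)$; the agonist
term bounds it by 2. The response is non-decreasing in $L$, $R$, $AG$, $CS$
and non-increasing in $AN$, $CI$. Whether a given study enables cofactor
modulation is rarely reported; the package keeps it on by default
(`useCofactors = TRUE`) and every cofactor list may be empty, in which case
the factors reduce to 1.

## Permutation significance

Each (sender, receiver, interaction) triple is assigned a p-value by
shuffling cell-type labels across cells (`nPerm = 100` by default),
recomputing summaries, the 20% filter and strengths each time, and counting
permuted strengths at least as large as the observed one. The add-one
estimator $p = (1+k)/(1+n)$ avoids zero p-values at finite $n$, and the
inclusive tie rule makes the test conservative; a zero observed strength
reports $p = 1$ by construction. In the per-sample design the shuffling
happens within each sample because each sample is inferred independently.
Only triples with $p < \alpha$ (default 0.05) count as detected
communication.

## Pathways, information flow, contributions

Every interaction belongs to exactly one signaling-pathway family. The
pathway score of a cell pair is the sum of its significant interaction
strengths; the information flow of a pathway is that score summed over all
cell pairs, and the relative information flow between two conditions
normalizes each pathway's flows to sum to one. Pathways with flow in
exactly one condition are labeled condition-specific. Outgoing (incoming)
cell-type contributions sum pathway scores over receivers (senders);
their columns conserve the pathway flow exactly, which the test suite
checks as an identity.

# The two differential designs

**Global approach.** All cells of each condition are merged, communication
is inferred once per condition over the cell types present in both, and the
package reports per-cell-pair differences in significant interaction counts
and total strengths plus a per-pathway paired Wilcoxon signed-rank test
over the cell-pair score vectors (pairing by identical cell pair, zeros
included; the choice of a *paired* test is this package's reading of an
otherwise unspecified "Wilcoxon test" at the pathway level, since the two
conditions are scored on the same cell-pair grid).

**Sample-by-sample approach.** Inference runs independently within each
sample, yielding pseudo-bulk sample-by-pathway and sample-by-L-R-unit score
matrices. Pathways identified (score > 0) in fewer than 5 samples across
both groups are removed — one identified in exactly 5 is retained. Each
retained unit is tested with a two-sided Wilcoxon rank-sum test between the
groups (exact when there are no ties, which holds almost surely for
continuous scores; normal approximation with tie correction otherwise),
with BH FDR within each family (pathways; L-R units). Fold changes use
$(\bar x_A + \varepsilon)/(\bar x_B + \varepsilon)$ with $\varepsilon$ =
smallest positive score $\times 10^{-3}$, reported alongside group means
and SDs. Detection in a sample is defined as a positive post-significance
score because no alternative definition is available for this design.
An explicit sample-to-group map (`groupMap` in `runPipeline()`) re-runs the
same design on any regrouping, such as a balanced 4-versus-4 split used as
a middle ground between the two designs.

Sample-level PCA (centered, unscaled) summarizes between-sample structure;
variance fractions sum to one. Subsampling robustness re-runs the global
comparison on random cell subsets (default 50% of cells, 10 repeats) and
reports the correlation of the subsampled strength differences with the
full-data differences; the full run and every repeat share one permutation
seed so that a 100% "subsample" reproduces the full result exactly.

# Communication patterns by NMF

The cell-type-by-pathway signaling matrix (outgoing or incoming, pathway
columns scaled to unit maximum) is factorized as $M \approx WH$ with
multiplicative updates under the Frobenius objective, seeded uniform
initialization scaled by the matrix mean, and at most 200 iterations for
the final fit (a non-converged fit is returned with a warning flag). Rows
of $W$ are normalized to sum to one so each cell type distributes its
loading over patterns.

The number of patterns $k$ is selected from consensus clustering: 30 NMF
runs per candidate $k$ assign each cell type to its dominant pattern, the
co-clustering frequencies form a consensus matrix, and two diagnostics are
computed from its distance structure — the cophenetic correlation of the
average-linkage dendrogram and the mean silhouette width of the consensus
partition. The literature names these metrics without fixing a decision
rule, so the package documents its own: the chosen $k$ is the largest
candidate with both metrics at $\ge$ 95% of their value at the smallest
candidate, falling back to the cophenetic maximizer; both metric profiles
are always returned so users can override $k$. Thirty runs per candidate
keep the consensus estimates stable at the matrix sizes involved (tens of
cell types and pathways). All loadings are reported; no cell types are
omitted from the output on minor-contributor grounds.

# Downstream enrichment statistics

*Overrepresentation* uses the hypergeometric upper tail
$P(X \ge k)$ against each gene set, with BH correction across sets. The
default universe is the genes present in the expression matrix, a choice
the package makes explicit because published analyses often leave it
unstated; it is configurable, and reported odds ratios depend on it.
*Gene-list overlap* builds the 2x2 table against the universe and reports
the sample odds ratio $(ad)/(bc)$ — with a Haldane 0.5 correction when any
cell is zero — and the two-sided Fisher exact p-value. With a large
universe the correction keeps a zero-overlap odds ratio finite but not
necessarily below one; the direction call should therefore rest on the
table, not the corrected point estimate. *Preranked GSEA* implements the
classic weighted Kolmogorov-Smirnov running sum (weight 1 by default) on a
fold-change-ranked gene list, with a gene-label permutation null (set
positions redrawn uniformly), NES normalization by the mean same-sign null
magnitude, and the standard positive/negative pooled-null FDR; the
conventional FDR < 25% flag is the default for this statistic. Gene-label
permutation is the appropriate null for a preranked list, where phenotype
permutation is unavailable. GO hierarchies and term-redundancy clustering
are out of scope; sets are supplied flat (GMT).

# Spatial co-expression

Given a spot-by-gene matrix with layer labels, the Pearson correlation of
each L-R gene pair is computed across all spots or within one layer
(layers with fewer than 10 spots are skipped with a warning). Complexes are
expanded into every ligand-subunit x receptor-subunit gene pair and
flagged, since subunit-level correlation is the observable quantity in
spatial data. The null is the correlation distribution of uniformly drawn
random gene pairs excluding the true pairs; the package quantifies the
visual density-plot comparison with a two-sample Kolmogorov-Smirnov
statistic, and the test suite additionally uses a one-sided Mann-Whitney
test for stochastic dominance of the true-pair correlations.

# The synthetic-data generator

The generator emulates the study design the pipeline targets: 17 cortical
cell types, 13 case versus 10 control samples, and a draw of 40-60 cells
per type per sample (about 19,000 cells in total). Counts are negative
binomial (size 4, moderate overdispersion as seen for reasonably expressed
genes in UMI-based snRNA-seq), library-normalized per cell to the median
depth and log2(1+x)-transformed — generating counts rather than expression
directly means the 20% detection filter is exercised on realistic zeros.

Database genes are cell-type-structured: each interaction receives a home
(sender, receiver) pair; its ligand genes are elevated in the home sender
and receptor genes in the home receiver (mean 3.2 counts, clearly above
the detection threshold at these depths), while off-home expression sits at
mean 0.05 counts, clearly below it. Keeping off-home expression well away
from the 20% boundary is deliberate: baseline expression near the boundary
makes detection flicker across samples and buries planted effects under
filter noise that has nothing to do with the biology being modeled.
Cofactor genes are broadly expressed. Planted signals scale the ligands of
selected pathways by a chosen fold change (default 2) in the home sender of
one condition's samples; receptors are elevated in both conditions, so the
differential is purely ligand-driven. Per-sample log-normal gene-level
effects (SD 0.25 of the mean) create the between-sample variability that
makes the pseudo-bulk tests non-trivial. The truth table lists every
planted differential.

What the generator does *not* emulate: batch and chemistry effects,
doublets, dropout beyond NB zeros, correlated gene programs, or
cell-type misannotation. Passing tests on synthetic data therefore
demonstrate the statistical machinery under its stated assumptions, not
robustness to those real-data complications.

# Numerical and design choices

- Gene symbols are matched case-insensitively by uppercasing both sides;
  database genes absent from the matrix are treated as zero expression with
  one aggregated warning.
- The complex-subunit delimiter is `_` (configurable), matching common L-R
  resource conventions; multi-pathway interaction membership is rejected at
  load so pathway scores remain a partition sum.
- Cofactors are stored as flat gene lists, not complexes, because curated
  resources annotate them as soluble factors and co-receptors without
  complex structure.
- Permutation ties count against significance (inclusive `>=`), and the
  add-one p-value estimator keeps p > 0 at finite permutation counts.
- The exact Wilcoxon distribution is preferred whenever ties are absent;
  at 13-versus-10 samples its attainable level just below 0.05 gives a
  realized type-I error near 0.047, comfortably inside the calibration
  band the test suite enforces.
- NMF multiplicative updates stop at a relative error improvement below
  1e-6; the error trace is non-increasing up to machine precision, which
  the suite asserts.

# Problem sizes used by the test and acceptance runs

The suite exercises the full study scale where it matters and smaller
fixtures elsewhere, as its own choice of experimental design: end-to-end
recovery uses the default generator (30 pathways, 5 planted, 13 vs 10
samples, ~850 cells per sample) over 20 seeds; permutation-null calibration
uses 500 independent triples on exchangeable-label data (each triple with
its own permutation stream, so the uniformity test sees independent
p-values); pseudo-bulk type-I error and power use 1000 and 100 directly
simulated sample-level score vectors, whose distribution is all the
rank-sum test depends on; pattern recovery uses 10x8 two-block matrices
over 20 seeds; spatial dominance uses 50 planted pairs at correlation 0.5
across 200 spots.

# Known limitations

- Network-role analytics (sender/receiver/mediator/influencer centralities)
  and manifold learning over pathways are not implemented; contribution
  sums are the only cell-type-level summary.
- Regions (e.g. two cortical areas) are handled as separate runs, not a
  meta-analysis; no covariate adjustment or mixed models on the pseudo-bulk
  scores.
- The mass-action parameters are not fitted; $K_h$ is a fixed constant on
  the normalized log scale, so strengths are comparable within a run but
  not across differently normalized datasets.
- Real curated L-R databases are not shipped; `readLRDatabase()` documents
  the flat TSV schema into which CellChatDB- or CellPhoneDB-style resources
  can be exported.
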