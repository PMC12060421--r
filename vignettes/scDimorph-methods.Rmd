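---
title: "scDimorph: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{scDimorph: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models
and their assumptions, the parameters that matter and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the places where the design was genuinely open
and a choice had to be made. Quantitative claims made here are the
ones the test suite and `scripts/acceptance.R` compute; nothing is
asserted that the code does not itself verify.

## 1. Study design and data model

The pipeline targets 2×2(×age) designs: sex (M/F) × genotype (TG/WT),
optionally at two ages, with several mice ("samples") per group and
hundreds to thousands of cells per mouse. The central container,
`CellExpressionMatrix`, couples a sparse gene × cell integer count
matrix with per-cell metadata; QC statistics (`n_features`,
`total_counts`, `pct_mito`) are always recomputed from the counts so
they cannot drift out of sync. Mitochondrial genes are recognized by
the standard mouse `mt-` prefix.

## 2. Quality control and normalization

Cells are removed when they have fewer than 200 detected features
(likely empty droplets), more than 7,000 (likely doublets), or more
than 5% mitochondrial counts (likely stressed or dying cells). The
wording of these rules is exclusionary ("fewer than", "more than",
"greater than"), so all boundaries are inclusive on the kept side: a
cell at exactly 200 features or exactly 5% mitochondrial content is
retained. Filtering is idempotent.

Normalization is a fully specified stand-in for regularized-model
approaches: `log1p(count × median_depth / cell_depth)`. The choice is
deliberate — every downstream test statistic operates on *counts* with
a depth offset, so the normalization only feeds variable-gene
selection, clustering and annotation, where its fine structure matters
little, and a closed-form rule is auditable. Highly variable genes are
ranked by dispersion (variance/mean of normalized values) standardized
within quantile bins of the mean (20 bins, at least ~20 genes per bin;
with fewer genes the bin count shrinks), which removes the
mean–dispersion trend; the default of 2,500 HVGs matches common
practice for cortex-scale data. The scaled matrix is the per-gene
z-score of normalized HVG expression, clipped at ±10.

## 3. Dimensionality, clustering, annotation

The PC count is chosen by an elbow rule: the smallest *k* where the
change in variance explained from PC *k* to *k*+1 drops below 0.1%.
"Change" can be read two ways; the default is the **relative** change
`(v_k − v_{k+1})/v_k`, with the absolute percentage-point difference
available via `mode = "absolute"`. Both are implemented because the
rule's common verbal statement does not distinguish them.

Clustering builds a k-nearest-neighbor graph (k = 20, neighborhoods
include the cell itself) in PC space, weights edges by Jaccard overlap
of neighborhoods (SNN), and runs Louvain modularity optimization over
a geometric grid of 15 resolutions in [0.001, 1]. The partition
maximizing mean silhouette width (Euclidean, PC space) is returned;
single-cluster solutions get silhouette −1 so they are only chosen
when nothing else exists. The community-detection seed is fixed before
every run; identical coordinates degenerate to one cluster with a
warning.

Annotation scores each cell against marker sets. Marker specificity is
`w_g = 1 − (t_g − 1)/(T − 1)` (`t_g` = types listing the marker, `T` =
number of types); markers below the sensitivity threshold 0.5 are
discarded. A cell votes for its top-scoring type when that weighted
z-score sum is positive; a cluster is assigned a type only when the
winning type's votes exceed 25% of the cluster, otherwise it is
`"Unknown"`. The published description of this scoring scheme leaves
the cluster-level aggregation open (summed cell scores vs. cell
votes); we use cell votes because the 25%-of-cells rule reads most
naturally as a count criterion, and because votes are robust to a few
extreme per-cell scores.

## 4. Differential expression

Per gene, stratum and sex, counts follow a Poisson log-linear model
with a library-size offset; the genotype effect is tested by a
likelihood-ratio test (χ², 1 df). For a two-group comparison this
model has closed-form maximum-likelihood estimates (fitted group rate
= total counts / total offset), which the implementation uses —
vectorized across genes — instead of iterative fitting; tests verify
agreement with `stats::glm` and with a brute-force profile-likelihood
grid. Reported log₂ fold changes use depth-normalized group means with
stabilizer ε = 1/n_cells and are capped at |log₂FC| = 25 with a flag,
because genes expressed in only one condition otherwise produce
arbitrarily extreme estimates.

**Composition correction.** Observed library sizes are not neutral
normalizers: when a sizable fraction of genes genuinely changes in one
condition, that condition's library sizes absorb the shift and every
*unchanged* gene acquires an apparent opposite fold change. At the
simulation scales used here (up to a third of genes planted at
|log₂FC| = 1.5) this inflates the null type-I error severalfold.
`run_stratified_de` therefore recenters the TG group's offset total so
the median log-ratio across co-expressed genes is zero — the same
"most genes are unchanged" assumption that underlies median-of-ratios
and TMM normalization — before testing, and `test_interaction` applies
the correction within each level of the other factor so composition
cannot masquerade as an interaction. The correction is skipped when
fewer than 20 genes are co-expressed, and it intentionally does *not*
apply to the single-gene `fit_gene_poisson`, which has no information
to estimate it. The assumption's limit is explicit: a true global
shift affecting more than half of expression would be partially
absorbed.

Under the null generator (2,000 genes, 200 cells/group) the empirical
type-I error at nominal 0.05 is ~0.05 for the genotype LRT and ~0.04–
0.06 for the interaction LRT (recomputed by the acceptance script).

Sex×genotype and age×genotype interactions are tested with one
coherent model family: the saturated 2×2 Poisson model (closed form)
against the additive null, which has no closed form and is fitted by
iterative proportional fitting on the 2×2 group totals (vectorized
across genes, tolerance 1e−12, ≤200 iterations; agreement with
`stats::glm` is tested). The reported interaction effect is the
difference of the two genotype log₂ fold changes. The age-dependent
analysis is operationalized as the age×genotype interaction fitted per
sex — one defensible reading of an age-dependent contrast when the
original model is not fully specified.

"Pseudobulk" means all cells pooled into one cell-level analysis, not
per-sample summation, mirroring the phrase "across all cell types
integrated"; cell-level testing ignores between-mouse correlation,
which is a known limitation (Section 9). Genes detected in fewer than
3 cells in both genotype groups are pre-filtered; BH adjustment is
applied within each (stratum, sex, comparison) table, matching
per-table FDR reporting. BH itself is implemented directly (step-up
with running-minimum monotonicity) and tested against `p.adjust` on
1,000 random vectors.

## 5. Sex-dependence classification

With `sig_s = (FDR_s < 0.05 AND |log₂FC_s| ≥ 0.5)`: sex-neutral =
significant both sexes, same sign; sex-dimorphic = significant both
sexes, opposite signs, with the redundant guard |log₂FC_M − log₂FC_F|
≥ 0.5 (implied when both effects exceed 0.5 with opposite signs, but
kept because both conditions appear in the published statements of the
rule); sex-specific = significant in exactly one sex while the other
shows *no nominal trend* (p > 0.5). Everything else is retained as
`unclassified` rather than silently dropped, for auditability. A gene
absent or untestable in one sex counts as showing no trend there, so a
gene expressed in only one sex can be called sex-specific.

The no-trend gate deserves emphasis. It is deliberately conservative —
it exists to prevent a gene from being called sex-specific merely
because its opposite-sex p-value wobbled above 0.05. The cost is a
hard sensitivity ceiling: for a *truly* sex-specific gene the
opposite-sex p-value is uniform on (0,1), so the gate passes only
about half of them, bounding one-vs-rest balanced accuracy near 0.75
no matter how many cells are sequenced. The acceptance computation
measures exactly this (~0.73–0.76 for the sex-specific categories,
≥0.99 for sex-neutral and sex-dimorphic, null false-calls ≤ 0.25% at
500 cells/group/sex and |log₂FC| = 1.5). Users who need sensitivity
over specificity can relax `nonsig_nominal_p_min`.

Age-dependence classification applies the same rules to the per-sex
age×genotype effects and, by default, reports only sex-dimorphic /
sex-neutral / unclassified, because a single interaction test per sex
rarely supports confident sex-specific age calls. Magnitude-only
interactions are reported separately and never merged into the
primary categories.

## 6. Enrichment

Over-representation uses the one-sided hypergeometric tail
`P(X ≥ k)`, identical to one-sided Fisher's exact test (verified to
machine precision on random configurations). The universe defaults to
the genes actually tested in the originating DE table — standard ORA
practice and the only choice that respects the detection pre-filter.
Sets are intersected with the universe before sizing; size bounds 3
and 500 exclude sets too small to test or too generic to interpret.
BP and MF namespaces are tested and BH-adjusted separately.

## 7. Network refinement and perturbation

Significant genes (FDR < 0.05, *no* effect-size filter — coordinated
small changes are the point of network analysis) are binarized:
increased = 1, decreased = 0; the control profile is the exact
complement. A prior network (TSV edge list; effects activation /
inhibition / unknown; interaction-category allow-list applied at read
time) is refined per condition by maximizing the number of
sign-consistent edges — activation demands equal endpoint states,
inhibition opposite — over a chromosome consisting of one bit per
latent (unmeasured) node state and one bit per unknown edge sign.
The objective counts consistent edges only, with no retention bonus:
edges inconsistent at the optimum are excluded with reason
`state-conflict`, realizing both required behaviors (edge exclusion
and sign inference) with the simplest well-posed objective. Whether
the original formulation also weights edges by evidence is not
recoverable; this objective is the documented choice.

The genetic algorithm uses tournament selection (size 3), uniform
crossover (rate 0.7), bit-flip mutation (rate 0.02), elitism (4), a
population of 200 and 300 generations — conventional values, chosen
once; elitism makes the best-fitness trajectory provably
non-decreasing, which is asserted on every run. Fitness evaluation is
vectorized over the population. A fixed seed makes runs bit
reproducible. Instances with nothing to search are solved exactly
edge-by-edge and flagged. `exhaustive_refine` enumerates all
configurations (refusing above 20 bits, chunked at 2^14) with ties
broken by lexicographic chromosome order; on seeded 12-bit instances
the GA matches its optimum 20/20 (recomputed by the acceptance
script).

Perturbation scoring flips a regulator (or a pair, seeded
simultaneously) to the complement of its disease state and propagates
breadth-first: a node is evaluated when the wavefront first reaches
it, against the snapshot of states finalized in earlier waves, so
results cannot depend on iteration order within a wave; agreeing
parent implications are adopted, conflicting ones mark the node
ambiguous (never counted, never propagated); finalized nodes are never
re-opened, which makes cycles safe. Unperturbed parents impose no
constraint — the analysis models deviation from the disease baseline,
not a full steady-state. The score counts downstream genes with a
measured disease state predicted to revert to the control state. On
DAGs where every affected node has a unique net path sign, this
provably coincides with sign-product path enumeration, and the tests
verify exact agreement of states, scores and rankings on 50 random
such DAGs. Pair scores are not guaranteed ≥ the best single score:
simultaneous seeding can create conflicts. Ranking is deterministic:
score, then smaller set, then lexicographic gene order; pairs are
drawn from the top-20 singles (beam search) to bound cost.

## 8. Behavior and power

An arm "entry" requires changing arms, so consecutive duplicates are
collapsed at ingest (making scoring idempotent); whether a re-entry
after exiting counts as a new entry is not standardized, and the
collapse convention is ours. A correct alternation is a window of
three consecutive entries visiting three distinct arms; the percentage
divides by entries − 2, the number of windows. Mice with fewer than 10
entries are excluded (exactly 10 is kept). The two-way ANOVA uses Type
II sums of squares because behavioral group sizes are typically
unbalanced (Type III is the documented alternative); the four planned
comparisons (within-sex genotype contrasts, within-genotype sex
contrasts) are computed on estimated marginal means and
Šidák-adjusted, `p_adj = 1 − (1 − p)^4`. Noise-free designs (zero
residual variance) are handled analytically rather than through the
general solver: effects with zero sum of squares report F = 0, p = 1.
Power for the two-sample t-test uses the noncentral t distribution
(ncp = d√(n/2), df = 2n − 2); at d = 2, α = 0.05, n = 11/group it
gives 0.9937, comfortably above the 80% design requirement.

## 9. The synthetic-data generator

The generator is first-class, tested code, and it defines the
conditions under which the pipeline's guarantees are measured. It
emulates: Poisson (optionally negative-binomial via a `dispersion`
knob) counts with gamma-distributed baseline means (shape 2, rate 2 —
mean 1 count per median cell, a realistic sparsity for cortex data);
log-normal library sizes (median 2,000, σ = 0.35) with per-sample
shifts (σ = 0.15) so the GLM's offset is genuinely exercised;
controlled mitochondrial content (per-cell target fraction uniform in
[0.5%, 3%] via rescaling of `mt-` genes); cell-type structure
expressed solely through 2–8× elevation of disjoint marker genes; and
planted TG-only effects per category — sex-specific, sex-dimorphic
(opposite signs), sex-neutral (equal signs), and magnitude-only
interactions (female effect = 0.25× male) — optionally active at one
age only. Poisson is the default because the DE test assumes it: the
test's assumed model should be the default null generator, with
overdispersion available to stress calibration (the data's true
generative law is, of course, not knowable from the test's model
alone).

It does **not** emulate: transcriptome-wide co-expression structure,
doublets, ambient RNA, batch effects beyond sample depth shifts, or
realistic marker biology. Passing tests therefore demonstrate
correctness of the *rules and statistics* under the stated model, not
robustness to every artifact of real droplet data.

The network generator plants an exactly known refinement optimum:
planted-inconsistent edges get the sign contradicting their measured
endpoints (chosen before latent nodes, which are drawn disjoint from
those edges, so no latent assignment can rescue them); all other edges
get the consistent sign; unknown-sign flags go only to reconcilable
edges. The behavioral generator chooses each next arm to complete an
alternation with the group's propensity, else revisits the arm two
steps back, so propensity 1 gives 100% alternation, 0 gives 0%, and
intermediate values give that exact expected fraction.

## 10. Problem sizes and numerical choices

Test and acceptance computations use: calibration at 2,000 genes ×
200 cells/group; category recovery at 2,800 genes (200 per planted
category) × 500 cells/group/sex; GA-vs-oracle on 20 instances of 12
nodes / 20 edges / 12 binary variables; 50 random DAGs of ≤ 15 nodes;
and an end-to-end run at 600 genes × 1,200 cells with four planted
cell types (annotation ARI ≥ 0.99 against truth). These sizes give
stable Monte-Carlo estimates while keeping the whole suite fast on a
single CPU. Other numerical choices: IPF tolerance 1e−12; GA and
community-detection seeds fixed; exhaustive-search tie-break
lexicographic; log₂FC cap 25; z-score clip ±10; silhouette −1 for
single-cluster partitions; HVG bins shrink below 400 genes and
vanish below 40.

## 11. Known limitations

Cell-level DE treats cells as independent, ignoring mouse-level
pseudoreplication; the composition correction assumes most genes are
unchanged; the sex-specific categories have the ~50% sensitivity
ceiling described in Section 5; the SNN/Louvain pipeline is exact only
up to graph-construction choices (k, Jaccard pruning); pair
perturbation is a simultaneous-seeding approximation with no
superadditivity guarantee; and symbol harmonization is a
case-fold-plus-alias-table rule, not an orthology mapping.
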