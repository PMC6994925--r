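---
title: "lipidnet: methods, models and design choices"
author: "lipidnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lipidnet: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidnet)
```

This vignette is the package's own account of the science it
implements: the models and their assumptions, the tunable parameters,
what the synthetic generator does and does not emulate, the numerical
choices, and known limitations. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## 1. Study design and data model

The pipeline targets paired omics from a five-group dietary study of
peripheral neuropathy: standard diet (SD), high-fat diet (HFD),
HFD + streptozotocin (HFD-STZ), and dietary-reversal arms (HFD-DR,
HFD-STZ-DR), sampled at 16 and 24 weeks; reversal groups exist only at
24 weeks because animals are switched back to SD at 16 weeks. Data
enter as feature-by-sample matrices (`omics_matrix`): a lipid intensity
matrix whose row ids follow the `CLASS(c1:d1/c2:d2[/...])` grammar over
17 lipid classes, and a gene count matrix, both tied to a sample sheet
(`sample`, `group`, `timepoint`).

Total-composition ids such as `TG(52:2)` are accepted: the class is
known but acyl chains are unresolved, so fatty-acyl summaries refuse to
guess a chain split and error instead.

## 2. Lipidomics preprocessing

**KNN imputation** (`knn_impute`, default `k = 10`). Neighbours are
lipid features; distances are Euclidean over mutually observed samples,
rescaled by $\sqrt{n_{total}/n_{obs}}$ so features with few shared
observations are not spuriously close. A missing cell is the mean of
the $k$ nearest features observed in that sample. Only missing cells
change. The order normalise-then-impute versus impute-then-normalise is
not uniquely determined by practice; this pipeline imputes first (raw
intensities carry the neighbourhood information), and the stages are
separate functions so the order can be changed.

**Internal-standard normalisation**
(`normalize_internal_standard`). Each lipid is divided, per sample, by
its class's internal-standard feature; standards are then dropped. The
standard map is user-supplied (a single global standard is allowed
under the name `"*"`); the synthetic generator emits one `STD_<class>`
feature per class. Zero standard intensity is an error, not a silent
NaN.

**Ion-mode merging** (`merge_ion_modes`). Species identified in both
positive and negative mode are collapsed to the arithmetic mean of the
two normalised rows; single-mode species pass through. The output has
exactly one row per unique species. More than two rows for one species
indicates an upstream id problem and errors.

**z-scoring** (`zscore_features`) uses the $(n-1)$ standard deviation
and is computed within each timepoint's sample set by default, matching
per-panel heat-map displays; a global transform is available.

**Summaries.** `class_sum` totals all species of one class per sample
(group mean ± s.e.m. reported); summing over all classes reproduces the
per-sample grand total exactly. `fa_composition` totals each fatty-acyl
chain weighted by its multiplicity within each species (one unit of
TG(16:0/16:0/18:1) contributes 2 to C16:0), and is linear in abundance.

## 3. Differential analysis

Lipids use the pooled-variance Student's *t*-test (`t.test(var.equal =
TRUE)`; Welch behind a flag), two-sided, with `log2FC =
log2(mean_A/mean_B)`; genes use a simplified negative-binomial Wald
test (`nb_wald_deg`): median-of-ratios size factors, per-gene
method-of-moments dispersion pooled within groups and floored at 1e-8,
a delta-method standard error under the NB variance $\mu + \alpha\mu^2$,
and a pseudocount of 0.5 on the group means. This is deliberately a
light stand-in for full RNA-seq machinery — no dispersion shrinkage, no
outlier filtering — because the pipeline's conclusions depend on
count-scale differential signals, not on a specific DE implementation.
Multiple testing uses Benjamini–Hochberg (`stats::p.adjust`) with
significance at adjusted $p < \alpha$ (default 0.05).

**Overlap classification** (`overlap_analysis`). "Common" features are
significant in both the disease comparison (disease vs control) and the
reversal comparison (reversal vs disease). Each is labelled by the
comparison in which its |log2FC| is larger: `increased_with_disease`
(disease dominates, positive), `decreased_with_reversal` (reversal
dominates, negative), else `discordant`. The published figures this
mirrors do not state their partition rule explicitly; both raw fold
changes are always retained in the output so alternative partitions can
be recomputed, and the rule is recorded here rather than hidden.
Cross-model commonality (`cross_model_common`) intersects the two
models' common sets and tallies lipid classes.

**Enrichment** is an upper-tail hypergeometric test per gene set
(`stats::phyper`), BH-adjusted across sets, universe defaulting to all
genes with non-zero counts. Gene sets use the standard GMT format
(read via `fgsea::gmtPathways`).

## 4. O2PLS

`o2pls(X, Y, K, nx, ny)` fits, on column-centred (ideally unit-scaled)
blocks:

$$X = T W' + T_{Yo} P_{Yo}' + E_X,\qquad
  Y = U C' + U_{Xo} P_{Xo}' + E_Y$$

1. $W, C$ = $K$ leading left/right singular vectors of $X'Y$;
   $T = XW$, $U = YC$.
2. X-side orthogonal part, extracted as a single block:
   $E = X - TW'$; $W_{Yo}$ = `nx` leading left singular vectors of
   $E'T$; $T_{Yo} = XW_{Yo}$; $P_{Yo} = X'T_{Yo}(T_{Yo}'T_{Yo})^{-1}$;
   deflate $X \leftarrow X - T_{Yo}P_{Yo}'$ and refresh $T$.
3. Symmetric Y-side step from $F = Y - UC'$.
4. Inner regressions $B_U = (U'U)^{-1}U'T$, $B_T = (T'T)^{-1}T'U$.
5. Variance partition from squared Frobenius norms of the joint,
   orthogonal and residual parts against the original $\|X\|_F^2$
   (and $Y$ analogue).

Because $W'(E'T) = 0$ algebraically, extracting $W_{Yo}$ from $E'T$
makes $W'W_{Yo} = 0$ (and $C'C_{Xo} = 0$) hold to machine precision,
and the three variance fractions sum to 1 up to roundoff — both are
asserted in the tests rather than assumed. Block extraction bounds
`nx, ny <= K` (the deflation operand $E'T$ has rank at most $K$); the
fit refuses larger requests rather than returning null-space
directions. Sign ambiguity of the SVD is fixed by making the
largest-magnitude entry of each $W$ column positive, flipping the
paired $C$ column with it. Singular inner matrices (rank deficiency)
produce an error suggesting fewer components.

**Defaults.** `K = 2, nx = 2, ny = 2` — six components in total, the
total used in the study this design emulates, which did not state the
joint/orthogonal split; the split is therefore configuration, and
`select_components` chooses it by 5-fold cross-validated reconstruction
error $\|X-\hat X(Y)\|^2 + \|Y-\hat Y(X)\|^2$ over a user grid, with
group-stratified, seed-deterministic folds and ties resolved towards
fewer components.

**Scaling** (`scale_transform`): `log2(x + 1)` then per-feature
centring and unit variance ($(n-1)$ convention). The pseudocount of 1
keeps zero counts at zero on the log scale.

**Transcript pre-filter** (`filter_transcripts`): genes with raw
$p <$ `p_keep` (default 0.05) in *any* comparison, union'd with the top
variance genes up to the `min_keep` floor (default 100) — the study
this emulates retained ~6000 of ~20k transcripts by differential
signal; the exact recipe was unstated, so both knobs are explicit.

**Candidates** (`top_loadings`): features ranked by the Euclidean norm
of their row of $W$ (or $C$) across the $K$ joint components, ties
broken lexicographically for determinism; 50 lipids and 100 genes by
convention.

## 5. Correlation network

`pearson_edges` computes lipid–lipid and lipid–gene Pearson
correlations across all samples of all groups and both timepoints (the
design does not restrict the correlation sample set; a subset can be
passed by slicing the matrices) and keeps $|r| > 0.6$. The threshold
alone defines "significant pairs"; an explicit correlation-test filter
was considered and left out to keep the operational definition exactly
the stated one. Gene–gene edges are never formed — the network is
lipid-centred — and this is asserted on every build. Network genes pass
a two-stage filter (`filter_genes_by_annotation`): annotated to at
least one network lipid in the user-supplied gene–lipid association
table (HMDB-style), then intersected with the O2PLS-retained
transcripts (`network_gene_pool = "retained"`; the top-100 candidate
list is the alternative pool, since either reading is compatible with
the source description — both stage counts are reported either way).

**Subnetworks** (`detect_subnetworks`): greedy-modularity communities
(igraph `cluster_fast_greedy`, unweighted, on the lexicographically
ordered simple graph) by default, connected components as a
sensitivity mode. The greedy split is kept only where it strictly beats
the component partition on modularity, so degenerate graphs (e.g. a
single edge) resolve to the coarser, unambiguous answer. Subnetworks
with at least `max(24, ceil(0.10 * nodes))` members are flagged
"large". **Reversal annotation** colours each node by its common-DAL /
common-DEG status: `reversed_up_in_disease` for positive disease
log2FC, `reversed_down_in_disease` for negative, `not_reversed`
otherwise; direction conflicts across the two disease models resolve
to the larger |log2FC| and are logged.

## 6. The synthetic study generator

`simulate_study` produces everything downstream stages consume, plus
ground truth sufficient to score recovery.

- **Lipidome**: log-normal intensities, class-specific baselines over
  the 17 classes (TG-dominated composition), per-sample residual s.d.
  0.5 log2 units. A fraction `fraction_tg_affected` (default 0.5) of
  TG and DG species — preferring species carrying saturated 16:0/18:0
  chains, so fatty-acyl summaries respond — is shifted up by
  `disease_effect_size` (default 1 log2 unit) in HFD and HFD-STZ at
  both timepoints and left at SD level in the DR groups. A
  configurable 15% of species appears as duplicate positive/negative
  ion-mode rows; one internal standard per class is appended; entries
  are deleted completely at random at `missing_rate` (default 5%).
  MCAR is an assumption — the emulated study reported only that
  missing values existed — so the rate and mechanism are parameters,
  not claims about the original data.
- **Transcriptome**: negative-binomial counts, log-normal gene means,
  common dispersion 0.05 (0 gives the Poisson limit), library sizes
  ±30%; `n_affected_genes` (default 60) genes carry the same
  disease/reversal pattern.
- **Planted joint factor** (`plant_joint_factor`): a per-sample latent
  score $s$ = standardized disease indicator + N(0, 0.3), times sparse
  positive loadings of scale `joint_factor_strength` (default 2.5
  residual-s.d. units) over 50 designated TG species and 30 designated
  genes. The support is drawn preferentially from the disease-affected
  features: the factor emulates the disease axis itself (the TG /
  TG-synthesis-gene module), so planting it on features disjoint from
  the disease effect would create two competing joint axes and
  misrepresent the structure the integration is meant to find. The
  factor is applied on the log2 scale (counts are multiplied by
  $2^{s w}$ and rounded), so strength 0 is exactly the identity and
  counts remain counts.
- **Annotation**: a pair table linking ~100 genes to lipids, always
  linking the planted genes to planted lipids, plus GMT gene sets of
  which one coincides with the affected-gene set (the enrichment
  positive control).

Acyl-chain pools: TG/DG species draw from
{16:0, 16:1, 18:0, 18:1, 18:2} extended with four minor chains so 145
distinct TG species exist; single-chain and phospholipid classes use a
broad pool with saturation-dependent double-bond limits; ids are
canonicalised with chains in ascending (carbons, double-bonds) order.

All outputs are fully determined by `seed` (per-module substreams at
fixed offsets), and the ground-truth record (affected species/genes,
planted support, latent scores, dual-mode species) ships with the data.

**What the generator does not emulate**: batch effects, within-animal
longitudinal correlation, missingness mechanisms other than MCAR,
adduct/isotope artefacts, gene–gene co-expression beyond the planted
module, and realistic mean–dispersion trends. Passing tests therefore
demonstrate correctness of the pipeline's computations and its ability
to recover planted structure under idealised noise — not robustness to
those real-data complications.

## 7. Numerical and degenerate-input choices

- Zero within-group variance with equal means errors in the *t*-test
  (no arbitrary p); unequal means with zero variance give $t = \pm\infty$,
  $p = 0$.
- Constant features error in z-scoring and `scale_transform` (named in
  the message) and are skipped with a message in `pearson_edges`.
- All-zero genes are dropped and reported by `nb_wald_deg`; the
  pipeline harmonises the gene universe across comparisons first so
  overlap sets are well defined.
- Duplicate feature ids error at I/O; duplicate network edges collapse
  to the first correlation; duplicate annotation pairs collapse.
- BH inputs outside [0, 1] error.
- `top_loadings` ties break lexicographically; k beyond the feature
  count truncates with a warning.

## 8. Problem sizes used in the validation suite

The acceptance checks run the generator at the emulated study's scale
(578 lipid species; 2000-gene transcriptomes for the recovery study,
48 samples) over 20 seeds for factor recovery and 50 seeds for the
null-configuration controls; algebraic O2PLS invariants use random
20×15 / 20×12 blocks; unit tests use smaller fixtures (~100–200
features) chosen to keep the default test run fast while exercising
every code path. The full-scale default configuration (578 lipids,
6024 genes, 10 samples per group) is exercised once per acceptance run.

## 9. Known limitations

- The NB Wald stand-in is anti-conservative for very low counts and
  small groups compared to shrinkage-based DE methods; it is meant for
  planted-signal recovery and funnel counts, not for publication-grade
  DEG lists.
- O2PLS standard errors are not provided; inference on loadings is by
  ranking, not testing.
- The KNN imputer is $O(p^2)$ in features; fine at shotgun-lipidomics
  scale (hundreds of species), not intended for transcriptome-scale
  imputation.
- Greedy modularity can merge small communities attached to large ones;
  the components mode and the reported sizes table make this visible.
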