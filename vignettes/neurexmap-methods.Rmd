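---
title: "Methods: from regional expression to structural overlap and set-based association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from regional expression to structural overlap and set-based association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurexmap)
library(dplyr)
```

`neurexmap` implements an imaging-transcriptomics workflow that asks three
linked questions about a panel of disease-candidate genes (the motivating
application is bipolar disorder): do the genes share brain-wide expression
patterns; do those patterns sit near the structural abnormalities reported
by the MRI literature; and do genes co-expressed with a candidate gene
themselves carry genetic risk? This vignette describes each model, the
parameters that matter, and the design decisions taken where the underlying
procedures are usually left under-specified.

## 1. Expression clustering across brain regions

The input is a genes-by-regions expression matrix per donor brain, each
region carrying stereotactic mm coordinates. Probes are collapsed to genes
by the arithmetic mean (`collapse_probes()`; a max-variance-probe rule was
considered and rejected because it makes the gene profile depend on a
single probe's noise). Each gene is then Z-normalised across regions
(`zscore_genes()`, sample SD with the $n-1$ denominator), so downstream
quantities express relative regional enrichment.

Genes are clustered by agglomerative single linkage (nearest neighbour)
under the correlation distance $d(g,h) = 1 - r(g,h)$. Correlation distance
is used because the scientific claim behind a cluster is "these genes rise
and fall together across anatomy", and reported clusters are summarised by
their pairwise correlations. Ties in the merge order are broken by the
lexicographically smallest gene pair, which makes the dendrogram fully
deterministic.

**Cutting the dendrogram.** The default cut is at correlation-distance
height 0.7, i.e. genes join a cluster only through links with $r > 0.3$.
Under single linkage a cut at a fixed number of clusters $k$ is the wrong
tool for this problem: unrelated genes chain onto one another at heights
near 1, so any small-$k$ cut of a panel that mixes clustered and
non-clustered genes returns one giant component plus a few singletons. A
height cut instead separates genuinely correlated groups (within-cluster
$r \approx 0.4$–$0.8$ in both the reference data and the generator's
output) from noise genes, whose strongest chance correlation over ~900
regions stays far below 0.3. Explicit-$k$ and silhouette-selected cuts
(`cut = "k"`, `cut = "silhouette"`, $k \in [2, 8]$) remain available for
matrices without a noise background.

**Two-donor consensus.** A cluster is only trusted if it reproduces across
donors: two genes are consensus-co-clustered iff they are co-clustered in
*both* brains. Because the intersection of two equivalence relations is an
equivalence relation, consensus clusters are simply the groups of genes
with identical label pairs; groups smaller than `min_cluster_size` (default
2) are declared unclustered. This is deliberately conservative — a gene
that switches partners between donors drops out rather than being assigned
by majority.

**Mapping.** For each consensus cluster, per-region mean Z-scores are
averaged between homologous left/right regions (nearest mirrored
coordinate within 2 mm), mirrored to both hemispheres, splatted to the
nearest voxel of a 2 mm grid and blurred with an isotropic Gaussian of
FWHM 12 mm whose peak is normalised to 1, so an isolated region keeps its
Z value. Peaks and troughs are local extrema over the 26-neighbourhood
with $|Z|$ above a threshold (default 2 — a conventional two-SD cut; the
literature this emulates never quantifies its mapping threshold) retained
greedily in descending $|Z|$ with a 12 mm minimum separation.

## 2. ALE meta-analysis of structural foci

Published VBM studies report peak coordinates ("foci") per contrast
direction. Activation likelihood estimation treats each focus as an
isotropic 3D Gaussian probability that the true peak lies in a voxel;
the per-focus probability is the Gaussian **mass** in the voxel (density
times voxel volume, clipped at 1), which keeps the union formula
$\mathrm{ALE}(v) = 1 - \prod_k (1 - p_k(v))$ a genuine probability. The
default pools over all foci of all studies (the original formulation of
the statistic, matching the random-foci permutation test below);
`pooling = "by_study"` first unions each study's foci into a
modelled-activation map.

Kernel widths follow study size: FWHM interpolates linearly from 9 mm at
the smallest sample to 8.5 mm at the largest (clamped outside the range).
The interpolation rule itself is a package choice — only the endpoint
range is conventional. MNI-space studies are brought to Talairach space by
the piecewise-linear Brett mapping (`mni_to_tal()`).

Significance uses a permutation null of randomly generated foci: each of
`n_perm` permutations (5000 by default; scaled runs in the tests use 200)
places the same number of foci with the same kernel widths uniformly on
mask voxel centres — no assumption about their spatial distribution or
separation — and all mask-voxel ALE values are pooled into a single null
histogram, matching the exchangeability assumption of the random-foci
test (per-voxel nulls would model inhomogeneous null density, which the
random-foci design explicitly does not). Voxelwise
$p = (\#\{\mathrm{null} \ge \mathrm{ALE}\} + 1)/(N + 1)$ is never exactly
zero. The pooled null sample grows as `n_perm` times the mask size; at the
default 5000 permutations on a 2 mm whole-brain mask it is large (~1 GB),
so scaled analyses should reduce the mask resolution or permutation count
together. Multiple comparisons are controlled by Benjamini–Hochberg
step-up with the independence constant, and surviving voxels are grouped
into 26-connected clusters with a minimum extent of 224 mm³ (boundary
retained at equality). Each cluster reports volume, peak ALE and peak
coordinate.

## 3. Anatomical overlap against a distance null

Proximity between an expression peak and an MRI result cluster is judged
against the empirical distribution of Euclidean distances between 200,000
random ordered voxel pairs drawn with replacement from a brain mask
(Euclidean distance is the only metric under which mm cut points are
meaningful; with ~10⁵ voxels the with/without-replacement distinction is
immaterial). The cut point at level $\alpha$ is the
$\lceil \alpha n \rceil$-th order statistic — an empirical quantile without
interpolation. On the package's Talairach-like ellipsoid mask (semi-axes
68/86/59 mm; the historical analyses never state their voxel universe, and
a grey-matter-only universe would shift the absolute cut points downward)
the cut points land near 26/15/12 mm for $\alpha$ = .05/.01/.005,
decreasing strictly with $\alpha$ and scaling linearly with the coordinate
scale. All cross pairs within the $\alpha = .05$ cut point are reported at
the most stringent level they satisfy.

## 4. Correlation-defined gene sets

For an index gene, every other retained gene is ranked by the Pearson
correlation of regional profiles. Donor handling is not specified by the
reference co-expression service, so the package z-scores per brain and
concatenates the region columns of both donors — this weights donors by
their region counts and avoids averaging correlations, which would need a
Fisher transform to be defensible. Sets are size-based only (no
correlation threshold): `top10`/`top25` are the index plus its 9/24
nearest genes, `top24` is `top25` with the index removed — the ablation
set that reveals whether an association rides on the index gene alone.

## 5. Set-based genetic association

Per-SNP association is the Cochran–Armitage trend test (1 df, additive
scores), computed as $N r^2$ with $r$ the phenotype–dosage correlation; a
logistic model would add covariate support but the cohorts in scope arrive
pre-cleaned and covariate-free. Within a set, markers are selected
greedily in ascending p-value order, requiring nominal significance
(`p_include`, default 0.05 — the conventional set-test default, the
reference analysis states none) and pairwise LD $r^2 < 0.50$ against all
previously accepted markers, with no cap on the accepted count. The set
statistic is the mean trend statistic over selected markers (0 if none
pass).

Inference permutes phenotype labels (default 10,000 permutations; scaled
runs use 200) and — crucially — re-runs the marker selection inside every
permutation, so the empirical p-value
$(1 + \#\{\mathrm{perm} \ge \mathrm{obs}\})/(n_{\mathrm{perm}} + 1)$ is
valid for the whole selection-plus-averaging procedure rather than for a
fixed marker list. Type-I error at $\alpha = 0.05$ is verified by
simulation in the acceptance suite.

## 6. The synthetic-data generator

Every stage is exercised on seeded synthetic data whose defaults mirror
the study conditions the pipeline is designed around: ~900 mirrored
left/right regions in two donors; 60 genes with planted clusters of sizes
9/9/4 (22 clustered genes); 18 imaging studies; 2200 cases and 1436
controls.

* **Expression.** Each planted cluster has a latent spatial profile built
  by smoothing white noise over the region coordinates with a 20 mm
  Gaussian kernel, which produces anatomically contiguous high/low
  territories. Latent profiles are orthogonalised over the sampled regions
  so distinct clusters share no signal and cross-cluster correlation stays
  near zero — comfortably inside the sub-0.2 regime the clustering
  assumes, and always below the within-cluster level. A cluster gene mixes
  its latent profile (weight $\sqrt{\rho}$, $\rho$ the target
  within-cluster correlation, default 0.6 — the centre of the 0.4–0.8 band
  the clustering is designed for) with gene-level noise shared across
  donors and donor-level noise at 25% of the gene-noise variance; the
  shared gene noise is what lets the two donors agree well enough for
  consensus clustering to succeed. A target of 1 switches all noise off.
* **Foci.** Each study reports each true locus displaced by isotropic
  Gaussian jitter (default SD 5 mm) plus uniform noise foci (default 3 per
  study), with subject counts uniform on 12–100 and a configurable
  proportion of contrast directions.
* **Genotypes.** One LD block per gene: latent haplotype liabilities
  follow an AR(1) with correlation `ld_block_corr`, thresholded at the
  block's allele frequency (one frequency per block, uniform on
  [0.1, 0.5] — common variants; equal thresholds keep the dosage
  $r^2$ of tightly linked SNPs close to the latent correlation, which
  thresholding would otherwise attenuate). Case/control status follows a
  logistic model with a per-allele log-odds effect at planted SNPs, and
  sampling continues until the case and control quotas are met exactly.

What the generator does **not** emulate: microarray probe chemistry and
batch effects, population stratification, genuine anatomical parcellation
(regions are uniform random points in an ellipsoid), inter-study
heterogeneity of MRI methodology, and the mild cross-cluster correlation
real expression modules can show. Passing tests therefore demonstrate that
the algorithms recover the structure they assume, not that real data
satisfy those assumptions.

## 7. Numerical choices and scaled problem sizes

All randomness funnels through one seed per entry point; stage sub-seeds
are derived deterministically, and two runs of the full pipeline from the
same seed produce byte-identical outputs (verified on uncompressed NIfTI,
TSV and Newick artefacts via the run manifest's MD5 hashes).

The automated checks run at reduced sizes chosen to keep the whole suite
within minutes on one core while leaving each property's signal-to-noise
ample: cluster recovery over 100 seeds at the full default configuration;
ALE calibration on a 64×76×64 mm mask at 2 mm with 200 permutations;
distance nulls at the full 200,000 pairs; set-test calibration over 500
null runs at 200 permutations and power over 50 seeds at 400 cases / 400
controls with an odds ratio of 1.3. Degenerate inputs fail fast with
informative errors (constant expression rows, empty clusters or masks,
monomorphic SNPs in LD computations, sets with no genotyped SNPs).

## Known limitations

* Single-linkage chaining makes the height cut sensitive to a single
  bridging gene; the two-donor consensus mitigates but does not remove
  this.
* The pooled ALE null assumes spatial exchangeability; masks with strongly
  inhomogeneous plausible-focus density would need the voxelwise variant.
* The distance null's absolute cut points depend on the voxel universe;
  only their ordering and scaling behaviour are universe-free.
* The set test's trend statistic ignores covariates and assumes additive
  allele effects.
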