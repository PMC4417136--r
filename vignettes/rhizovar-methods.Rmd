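---
title: "Methods: attributing soil community variation to species, chemistry, space and phylogeny"
author: "rhizovar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attributing soil community variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The question and the inference chain

Soil microbial communities under plant root zones vary from sample to
sample. Four non-exclusive explanations compete: the identity of the plant
species above the sample, the chemistry of the soil, the spatial position
of the sample, and the phylogenetic relatedness of the plants. `rhizovar`
implements a complete inference chain for weighing these explanations
against one another from an OTU abundance table (TRFLP-style relative peak
areas), per-sample metadata and chemistry, and a dated plant phylogeny:

1. **Preprocessing.** OTUs present in at most a threshold fraction
   (default 7%) of technical subsamples are removed — strictly: an OTU
   survives iff its presence fraction exceeds the threshold. Filtering is
   defined at the subsample level and therefore precedes subsample
   averaging; the two operations do not commute and the order is part of
   the contract. Technical subsamples are then averaged cellwise into one
   row per soil sample.
2. **Ordination.** Bray–Curtis dissimilarities
   $d_{ij} = 1 - 2\sum_k \min(x_{ik},x_{jk}) / (\sum_k x_{ik} + \sum_k x_{jk})$
   are embedded by non-metric multidimensional scaling (NMDS) minimising
   Kruskal's stress-1. The dimensionality $k$ is the smallest for which
   stress falls below a ceiling (default 0.20), read off a stress-versus-k
   profile.
3. **Ordination fit.** A permutation matrix regression (Mantel family)
   regresses the unfolded community distances on the Euclidean distances
   among ordination scores; its $R^2$, reported as a percentage, says how
   much of the community structure the ordination represents, with
   significance from simultaneous row/column permutations of the response
   matrix.
4. **Eigenvector predictors.** The species-level patristic distance matrix
   and the sample-level geographic distance matrix are each decomposed by
   principal coordinates analysis (Gower double-centering of squared
   distances, $G=-\tfrac12 C (D \circ D) C$). The leading seven
   phylogenetic axes (broadcast from species to their samples) and two
   spatial axes become linear-model predictors — the eigenvector-regression
   device that converts distance structure into ordinary design columns.
5. **Per-class models.** For each ordination axis, one linear model per
   predictor class: species identity (factor), genus (factor), soil
   chemistry, spatial location, phylogeny. Class significance and
   class explanatory power are computed on deliberately different designs
   (see below). Phylogeny and chemistry never share a tested model: at
   species level they are so collinear that joint fits produce variance
   inflation factors in the hundreds.
6. **Variance partitioning.** Three-set partitioning of each axis among
   phylogeny, chemistry and space on adjusted $R^2$: with $A_S$ the
   adjusted $R^2$ of the model on the union of sets $S$, unique fractions
   are differences such as $a = A_{123}-A_{23}$, shared fractions follow by
   inclusion–exclusion, and the residual is $1-A_{123}$. The eight
   fractions sum to one by construction; shared fractions may legitimately
   be negative and are reported, not clipped. Species identity is not a
   partitioning set — it is perfectly collinear with the full set of
   phylogenetic eigenvectors at species level.

# Selection versus testing

Two subset-selection steps make the reported models parsimonious: the
phylogenetic eigenvectors retained are those with coefficient $P<0.05$ in
the joint model of all seven screened phylogenetic axes plus the two
spatial axes; the chemistry subset comes from bidirectional AIC-stepwise
search started at the full ten-variable model, followed by refit-and-drop
pruning of terms with $P \ge 0.05$ (worst first).

A procedural point this package takes seriously: **testing a class on its
selected subset is anti-conservative.** If the class p-value were computed
by comparing the post-selection model to the intercept, a signal-free
response would be declared significant far above the nominal level (we
measured ~0.4–0.7 for the chemistry class under the null), because
selection has already optimised over the candidate set. `class_models()`
therefore separates the two roles:

* *significance* comes from the pre-selection screened sets — the overall
  F-test for the species and genus factors; the full ten-variable
  chemistry model against the intercept; whole-class drops of phylogeny or
  space from the joint (7 phylogenetic + 2 spatial) model;
* *explanatory power* (adjusted $R^2$) is reported from the parsimonious
  selected single-class models, with an empty selected set contributing 0.

Class drops use the likelihood-ratio statistic referred to its exact
Gaussian-linear-model null distribution (the partial-F reference) rather
than the $\chi^2$ asymptote: at $n=84$ the asymptote over-rejects
(measured 0.082 for a 10-parameter drop at the nominal 0.05).
`lrt_drop_class()` keeps the asymptotic reference as its default and
exposes `exact = TRUE`; the two are monotone transforms of each other and
agree as $n$ grows.

No multiplicity correction is applied across the axes-by-classes grid,
mirroring how such results tables are conventionally presented; users who
want familywise control can apply `p.adjust()` to the `p_value` column.

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `rare_threshold` | 0.07 | presence fraction | remove OTUs present in ≤7% of subsamples |
| `stress_ceiling` | 0.20 | stress-1 | usability ceiling for an NMDS embedding |
| `k_max` | 6 | axes | scan range for the stress profile |
| `n_starts` | 20 | — | one PCoA start plus 19 random starts |
| `n_perm` | 1000 | — | permutations of the ordination-fit test |
| `n_phylo_screen` | 7 | axes | screened phylogenetic eigenvectors (about half of 14 tips; `scree_break()` offers an automated alternative) |
| `n_spatial` | 2 | axes | leading spatial eigenvectors |
| `alpha` | 0.05 | — | retention / pruning level |

# Numerical choices

* **NMDS.** Stress-1 with monotone regression under the primary tie
  approach (tied dissimilarities may take unequal fitted values; ties are
  ordered by current configuration distance). Configuration updates use
  the Guttman majorisation transform; convergence is a relative stress
  change below $10^{-6}$ with a 500-iteration cap, and the best
  configuration seen is kept, so the returned stress never exceeds that of
  the PCoA start. Because NMDS solutions are defined only up to similarity
  transforms, scores are centred, rotated to principal axes, scaled to
  unit root-mean-square and sign-pinned (largest-magnitude score positive
  per column) — without this, bit-reproducibility and testability would be
  impossible.
* **PCoA.** Negative eigenvalues (legal for Bray–Curtis) are reported but
  their axes discarded without Lingoes/Cailliez correction, matching
  eigenvector-regression practice of using leading positive axes;
  eigenvalues below $10^{-8}$ of the largest are treated as null.
  Eigenvector signs are pinned as above.
* **Geography.** GPS coordinates are projected to planar metres by an
  equirectangular projection about the mean latitude (sphere radius
  6371 km). Over a few kilometres the distortion is far below the
  100 m site spacing. Spatial eigenvectors from PCoA of these Euclidean
  distances coincide with a PCA of the centred coordinates.
* **Determinism.** One master seed fans out to fixed per-stage offsets
  (tree, sites, chemistry, each community channel, NMDS starts,
  permutations), so changing one generator weight leaves every other
  random stream untouched, and two runs with one seed produce bit-identical
  output tables.
* **Degenerate inputs.** Readers reject rather than coerce: negative
  abundances, duplicate subsample keys, missing chemistry columns,
  unmatched Newick parentheses (reported with character offset), duplicate
  tip labels, pH outside (0, 14). All-zero abundance rows make Bray–Curtis
  fail loudly; collinear sites make the second spatial eigenvector an
  error; rank-deficient designs name their aliased columns.

# The synthetic-data generator

The generator is first-class, tested code: it is how every stage of the
chain is verified by parameter recovery in the absence of the field data.
The default design is a realistic congener-pair field campaign: 7 genera × 2 congeneric
species × 6 collection locations (84 samples), 2 technical subsamples,
150 OTUs, a 5 km square extent, within-species site spacing of at least
100 m.

For OTU $j$ and sample $i$ the log-affinity is
$$\eta_{ij} = w_{sp} a_{j,sp(i)} + w_{ch}\langle b_j, z_i\rangle
            + w_{sx} g_j(x_i,y_i) + w_{ph} t_j(sp(i)) + \varepsilon_{ij},$$
subsample rows add $N(0,\sigma_{sub}^2)$, and abundances are
$\exp(\eta)$ row-normalised — a log-linear composition model chosen
because TRFLP yields relative peak areas, so any weight setting produces
valid compositions. Each channel has roughly unit variance, so weights are
comparable; all four default to 1 with noise sd 1 and subsample sd 0.5.

Channel design decisions that matter:

* **Species vs phylogeny are separable by construction.** Species offsets
  $a$ are projected onto the orthogonal complement of the leading
  phylogenetic eigenvectors at species level, so the species channel
  carries the *non-phylogenetic* component of species identity, while the
  Brownian-motion channel $t_j$ (tip covariance equal to the tree's
  variance–covariance matrix) carries relatedness. The two can be injected
  independently — the crux of the comparison the package exists for. The
  converse direction cannot be separated: any phylogenetic signal *is* a
  species-level signal, so under a phylogeny-only scenario the species
  factor detects it too, necessarily.
* **Site patches.** Each species draws its sites from a species-specific
  Gaussian patch. Under the default `"random"` rule the patches are wide
  (sd = extent/3) and independent, so species identity carries almost no
  spatial information; the `"phylogenetic"` rule (shared genus centres,
  tight patches) is the switch for deliberately injecting space–phylogeny
  confounding.
* **Chemistry.** Each of the ten variables is a spatially autocorrelated
  Gaussian field (exponential covariance, range = extent/5) plus nugget
  noise, affinely rescaled to field-plausible marginals for a coastal
  loamy-sand site — pH 6.07 (sd 0.46, clipped to 5.01–8.03), organic
  matter 4.2% (sd 1.9, clipped to 0.6–15.5%), Na 91.8 ppm (sd 61, clipped
  to 12–390 ppm); the remaining seven variables have field-plausible
  means and spreads chosen once (they are not calibrated to a specific
  site). Because chemistry is spatially smooth, chemistry and space are
  *intentionally* confounded channels, as they are in any real landscape.
* **Community spatial fields** $g_j$ are broad-scale (range = extent/3):
  the analysis represents "space" by two leading distance eigenvectors,
  which are broad-scale trend surfaces, so the generator's spatial channel
  is given structure of the kind those filters can capture. A fine-scaled
  channel would be invisible to the analysis at any weight — a property of
  the two-eigenvector representation, not of the generator.

What the generator does **not** emulate: PCR or restriction-digest
artefacts, fragment-size binning error, primer bias, detection limits
(synthetic abundances are strictly positive, so the rare-taxon filter only
bites on real, zero-inflated data), non-Gaussian chemistry marginals, and
anisotropic or patchy spatial fields. Passing recovery tests therefore
demonstrates that the chain recovers the generating structure of this
model family, not that field data meet its assumptions.

# What the tests show, and what stays red

Unit and property tests cover every operation against independent oracles:
a brute-force double loop for Bray–Curtis, pseudo-inverse normal equations
for OLS, classical scaling for PCoA, independent subset enumeration for
the variance partition, closed forms for VIF, and the field-standard NMDS
implementation as a stress benchmark. Monte-Carlo problem sizes are stated
in the tests themselves (typically 100–500 replicates at $n=84$ for
calibration and recovery, 200 replicates of the full chain for the
signal-free calibration, 100 replicates per single-channel recovery
scenario at 60 OTUs).

Under the all-zero-weight world, every test the pipeline performs is
calibrated: per-class rejection rates 0.055–0.075 at the 0.05 level,
ordination-fit and likelihood-ratio tests likewise (the slight excess over
0.05 is intrinsic — responses are NMDS axes, not iid Gaussian draws).

Single-channel recovery finds the injected channel with power ≥0.98 and
the largest median adjusted $R^2$ of the four classes in three of four
scenarios. The assertions that remain red are structural consequences of
the generating conditions, not defects, and we keep them visible rather
than weaken them:

* chemistry-only and space-only scenarios cross-detect (both channels are
  spatially smooth — exactly the confounding that motivates the variance
  partition);
* species-level signals retain a small spatial footprint through the
  species site patches;
* under a phylogeny-only scenario the species factor necessarily detects
  the signal, and at high signal strength its median adjusted $R^2$
  marginally exceeds the phylogeny class's (logical nesting that the
  adjusted-$R^2$ penalty cannot close).

# Limitations

* The partial-Mantel-style ordination fit is implemented as matrix
  regression (multi-matrix capable); with one predictor matrix it is the
  squared Mantel correlation.
* The "visual break" used to pick seven screened eigenvectors is
  irreproducible by definition; the package defaults to the fixed
  first-seven with `scree_break()` as an automated alternative.
* Whether results tables should use per-axis AIC-selected chemistry
  subsets is a genuine reading choice; this package selects per axis.
* Variance partitioning operates on each ordination axis, not on the raw
  community matrix via constrained ordination; a joint multi-axis variant
  would weight axes by a convention the per-axis tables avoid.
* No PERMANOVA/ANOSIM, no phylogenetic GLS, no Moran-eigenvector spatial
  filter selection: the chain deliberately stays within the
  eigenvector-regression toolkit it implements.
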