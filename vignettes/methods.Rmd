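---
title: "Models and methods behind metastrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metastrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metastrack)
```

`metastrack` reconstructs the evolutionary and migration history of a
metastatic tumor from jointly called multi-sample sequencing data. This
vignette describes the models, the assumptions they rest on, the tunable
parameters and the numerical choices made where the design was genuinely
open. Everything quantitative asserted here is computed by the package's
test suite or by `scripts/acceptance.R`; this document explains *why* the
methods look the way they do.

## Somatic calling against matched normals

A variant is somatic when, in **every** matched normal sample, its allele
fraction is below `max_af = 0.1` *or* it has fewer than `max_alt = 5`
alternate reads. The two clauses guard against different failure modes:
low-level tumor-in-normal contamination (AF clause) and sporadic sequencing
errors at deep positions (count clause). A variant whose normal has zero
depth is `indeterminate`, not somatic — absence in the normal cannot be
asserted — and is excluded from downstream inference but retained in the
table.

Site filters follow strict inequalities as printed in their usual
formulation: site quality `> 30`, per-sample depth `> 15` (in every sample —
the conservative reading when the averaging scope is unstated),
accessibility mask inclusion, low-complexity exclusion, and removal of
multi-allelic sites. Masks are stored 0-based half-open (BED convention);
the variant table is 1-based (VCF convention); conversion happens once at
the mask boundary.

## Copy-number profiles and sample groups

Segment log2 ratios (FACETS-style output, consumed as input) are averaged
into 1-Mb windows weighted by overlap length; windows without coverage stay
`NA` rather than zero — a zero would fabricate a neutral observation.
Samples are clustered by UPGMA on Euclidean distances computed over the
windows non-missing in both samples. Groups are the clusters below the
largest gap in merge heights that additionally share at least
`shared_event_min = 2` discrete CNV events: maximal runs of windows whose
log2 values deviate beyond ±0.3 in the same direction in every member. The
event requirement keeps a cluster of merely *similar* profiles from being
promoted to a genetically defined wave; the ±0.3 log2 cutoff sits between
the one-copy gain (~0.58) and loss (~−1) levels at moderate purity. Both
thresholds are package choices, exposed as arguments.

## Allele-specific states and wave ordering

For an inherited heterozygous variant carried on $m$ of $c$ tumor copies in
a sample of purity $p$ (contaminating normal cells diploid and
heterozygous),

$$\mathrm{AF} = \frac{p\,m + (1-p)}{p\,c + 2(1-p)}.$$

At $p = 1$ this reduces to $m/c$ — e.g. 1/3 and 2/3 at total copy number 3,
and 0 or 1 under copy-neutral LOH; at $c = 2, m = 1$ it is 0.5 at any
purity. The purity generalization is the package's; it reproduces the pure
case exactly. `infer_allele_state_pair()` fits each sample's (major, minor)
copy split by nearest-expected-AF assignment and decides by majority vote
whether the major allele is the *same parental allele* in both samples.
Variants with AF in (0.4, 0.6) are excluded from the vote at LOH loci
(uninformative under noise), and a vote below 0.9 is an error rather than a
silent call. Balanced states (e.g. 1+1) leave haplotype identity
unresolvable; the concordance is `NA` and such pairs contribute no ordering.

Allele states order in time by the **no-resurrection rule**: state $X$ can
precede state $Y$ iff no allele at count 0 in $X$ is positive in $Y$. The
relation is a preorder (reflexive, transitive); states reachable in both
directions are reported `equivalent` and contribute no strict precedence.
Group-level wave ordering takes one representative sample per CNV group,
infers the paired state at the ordering locus, and keeps strict precedences
only; a cycle among precedences is a hard error naming the loci.

## Perfect phylogeny over samples

On copy-stable chromosomes, a somatic variant is present in a sample iff
its AF is strictly above 0.1 (an AF of exactly 0.1 encodes as absent — the
boundary must land somewhere, and the presence phrasing "greater than" is
taken literally). Variants with identical occurrence vectors are clustered;
under the infinite sites assumption every pair of clusters must have nested
or disjoint sample sets. Samples mixing divergent lineages (e.g. a primary
biopsy containing both an early and a late clone) break this; they are
detected greedily: the sample in the **intersection** of the most
conflicting cluster pairs is removed and clusters re-projected until no
conflict remains. The intersection heuristic matches the mechanism — a
mixture sample joins the sample set of both conflicting clones. Removal of
half the samples aborts: the data then violate infinite sites globally, and
no mixture annotation can rescue the model.

The perfect phylogeny itself is containment ordering: each cluster's parent
is the smallest cluster strictly containing its sample set; each sample
leafs under the smallest cluster containing it; branch lengths are variant
counts. Because a perfect phylogeny is equivalent to its laminar family of
sample sets, topology comparison in the validation suite is clade-set
equality. A UPGMA dendrogram on Hamming distances provides an independent,
constraint-free cross-check.

## Subclone reconstruction

### VAF clustering

Variants are partitioned by presence pattern (AF ≥ `af_positive = 0.05`),
then clustered within a pattern on their AF vectors. The clustering target
is simple — clusters that differ by less than `merge_tol = 0.1` in every
sample belong together — but binomial read noise at working depth makes the
naive implementations fail in characteristic ways, so the implementation is
staged:

* **Saturation capping.** For distance computation AFs are capped at the
  founding-clone level $p/2$: above it, AF carries no prevalence
  information, and uncapped saturated noise can split the truncal cluster.
  Reported mean AFs stay uncapped.
* **Two-stage agglomeration.** Complete linkage at the tolerance first
  over-segments each pattern into tight fragments; fragment means (noise-
  averaged) are then merged centroid-style. Merging raw variants directly
  lets single outliers chain two clones together.
* **Noise-adaptive band.** Fragments of a single clone are *thresholded
  pieces of one distribution* and sit up to roughly two binomial SDs apart
  by construction, so the stage-2 merge band is 1.3× the tolerance, widened
  to 3 pooled within-cluster SDs (capped at 2×) when read noise is larger.
* **Variance veto.** A merge is rejected when the merged cluster's pooled
  per-sample SD would exceed 1.5× the binomial SD at the pooled mean and
  the per-sample median depth — a spread read sampling cannot explain marks
  two genuine clones, however close their means.
* **Minor-cluster absorption.** Groups smaller than `absorb_frac = 0.3` of
  their pattern's largest cluster are read-noise strays and are absorbed
  into the nearest major cluster.

These choices were validated against planted ground truth; they are
heuristics for a problem (1-D mixture splitting with known noise scale)
that a fully Bayesian treatment would solve at far higher cost, which is a
deliberate non-goal.

### Prevalence and tree enumeration

Cluster mean AFs convert to cellular prevalence by
$CP = \mathrm{AF}\,(p\,C_t + 2(1-p))/(p\,C_v)$, capped at 1 — for the
default heterozygous copy-neutral case, $2\,\mathrm{AF}/p$. Variants inside
a group-shared one-copy deletion are supported with $C_t = C_v = 1$.

All rooted trees over the clusters are enumerated (recursive construction
with sum-constraint pruning; an independent Prüfer-sequence enumerator
serves as the test oracle). The root is the cluster within tolerance of
prevalence 1 in some sample that can dominate every other cluster; when
noise or conservative merging leaves no cluster that high, the dominating
cluster is accepted with a warning — aborting would discard an otherwise
well-formed reconstruction. A tree is valid when, in every sample, each
parent's prevalence plus `tolerance = 0.1` covers the sum of its children,
and each parent covers each child up to tolerance (lineage containment).
The violation of a tree is its total L1 slack; the chosen solution
minimizes it. Violations within half the tolerance of the minimum are
measurement-indistinguishable; among those the **deeper (more linear)**
topology wins: a child at the same prevalence as its parent in every sample
is a clonal sweep, not a coexisting sibling — the parsimony reading of an
inherently ambiguous signal. Ties after that resolve by deterministic
serialization. Enumeration is guarded at 12 clusters; beyond that the user
must raise `merge_tol`.

When the constraint set admits *no* tree, the cluster set is almost always
over-segmented; `reconstruct_subclones()` then merges the closest
same-pattern cluster pair and retries, up to three times, reporting each
merge.

## Migration classification

With per-site prevalences on the chosen tree ("atlas"):

* **Monoclonal seeding** — a subclone at partial prevalence in a harbor
  site (where it emerged) and at `full_threshold = 0.9` or above in another
  site seeded that site from the harbor. "100%" is operationalized as ≥ 0.9
  because noisy estimates never hit 1 exactly. A subclone with no harbor
  inherits its parent's source. Multiple harbors tie-break by subclone-tree
  proximity of the harbor's resident clones.
* **Polyclonal seeding** — subclones below `low_threshold = 0.5` in *both*
  sites of a pair, related as siblings or ancestor/descendant (or a lone
  such cluster: co-migrating siblings closer than the tolerance merge
  during VAF clustering, so a single low–low cluster is the same signal).
  The source is the site where the migrants' parents are more prevalent;
  parent prevalences within 0.05 cannot order the pair and resolve toward
  the primary site.
* **Recolonization** — at site $A$, an ancestor $X$ with standalone
  resident cells, a descendant $Y$ present, and at least one intermediate
  on the $X\!\to\!Y$ path that never stands alone at $A$ but stands alone at
  exactly **one** other site $B$ (exclusivity, the stricter reading),
  indicates $Y$ evolved at $B$ and invaded the established site $A$; the
  recolonizer must itself be absent at $B$ — if it is present at low
  prevalence at both sites, co-migration explains the pattern more simply.
  Multiple candidate origins are all reported and flagged ambiguous.
  "Standing alone" means standalone prevalence (prevalence minus children's
  prevalences) at or above 0.1.
* **Incubators** — a site harboring an ancestor–descendant chain of at
  least `min_chain = 2` subclones, each of which emerged there and seeded
  at least one other site from there.

The migration graph combines events, CNV groups and allele-state
precedences; inconsistencies (an unseeded non-primary site) are reported,
never silently fixed.

## The synthetic cohort simulator

`simulate_cohort()` emulates the study design this pipeline targets: a
primary site plus 8–30 metastatic sites sampled at one time point,
~45–60× sequencing, two matched normals, truncal/shared/private somatic
variants (Poisson mean 33 per branch, the typical per-subclone mutation
count at this scale), chromosome-scale CNV/LOH events, per-site subclone
mixtures expressed as standalone cell fractions (which satisfy the tree sum
constraints with zero slack by construction), purities, Poisson depths and
binomial alternate counts with a 1e-3 sequencing-error rate. Site
compositions come in three flavors: pure single-clone expansions (used for
noiseless phylogeny validation), "home sites" — one mixed site per subclone
with its parent lineage in the background, designed so the planted tree is
the essentially unique minimal-violation solution — and five scripted
seeding scenarios (`jumping_board`, `incubator`, `recolonization`,
`polyclonal`, `four_waves`) whose compositions realize the named pattern
exactly. The four-wave scenario additionally plants group-defining CNVs
(two discrete events per group) and a chromosome-3-style allele-state
ordering ((2,1) in wave 1; (2,0) in later waves) so that group detection
and wave ordering can be validated end to end. Scenario compositions keep
prevalence separations of pattern-sharing clones at or above ~0.35 and
standalone fractions of intermediates at or above 0.2, so the planted
pattern remains identifiable at 60× given the 0.1 tolerance; generic
cohorts draw purity from 0.6–1, scripted scenarios from 0.75–0.95 (the
high-purity samples such subclonal analyses are restricted to in practice).

What the simulator does **not** emulate — and what passing its tests
therefore does not establish for real data: realistic mutation spectra,
mapping and alignment artifacts, segmentation and purity estimation error
(purities are passed through exactly), subclonal copy-number changes within
the analysis chromosomes, kataegis-style clustered errors, and
contamination between samples. Mixture-sample flagging is exercised by the
scripted compositions only to the extent their lineages diverge.

## Expression support

Expression-based copy-number scores use `log2(TPM+1)` centered per gene
across samples, a center-aligned 101-gene moving average truncated at
chromosome ends, and per-gene subtraction of the mean windowed value over
normal samples; scores sit near zero in normals and deviate with dosage in
tumors. Chromosomes with fewer genes than the window are skipped with a
warning. RNA validation of genomic variants classifies eligible
observations (genomic VAF > 0.1, RNA depth ≥ 10): any alternate read
validates; otherwise genomic evidence in another expressing sample
validates in absentia; otherwise a binomial dropout probability
$P_0 = (1-\mathrm{VAF})^{\mathrm{depth}} > 0.05$ marks the observation as
plausibly unsampled; the remainder are not expressed. At VAF 0.1 and depth
10, $P_0 \approx 0.35$ — far too likely to call an absence.

## Validation scales

The default validation runs (tests and `scripts/acceptance.R`) use 200
noiseless cohorts of 5–15 subclones × 8–20 sites for phylogeny recovery,
500 random instances of ≤ 5 clusters for the enumeration oracle, 100
five-subclone home-site cohorts at 60× for prevalence RMSE and tree
recovery, and 65 scenario cohorts (15 at 200×, 50 at 60×) for seeding
classification — sizes chosen so the full suite completes in a few minutes
on one CPU while keeping the binomial sampling regimes of interest.

## Known limitations

* Subclone trees are identifiable only up to the information in bulk AFs; a
  child at exactly its parent's prevalence is topologically ambiguous, and
  the linearity preference is a heuristic, not evidence.
* The recolonization rule presumes the intermediates were sampled; an
  unsampled origin site makes the event invisible (mirrored by the fact
  that removing the origin site from a cohort removes the call).
* Greedy mixture-sample removal is validated against exhaustive search only
  for small removal sets; adversarial conflict structures could in
  principle mislead it.
* CNV-aware multiplicity deconvolution beyond the single copy-state
  correction, and Bayesian mutation clustering, are out of scope.
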