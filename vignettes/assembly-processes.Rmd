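---
title: "Inferring community assembly processes with assemblyproc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring community assembly processes with assemblyproc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`assemblyproc` partitions the pairwise turnover of microbial communities
into five assembly processes — homogeneous selection, variable selection,
homogeneous dispersal, dispersal limitation, and the undominated (drift)
regime — using phylogenetic and taxonomic null models. This vignette is
the package's account of the method: the models, the tunable parameters,
the numerical choices, what the synthetic generator does and does not
emulate, and the known limitations.

## The two-index framework

The inference works pairwise on samples of an OTU table aligned to a
rooted, branch-length-bearing phylogeny.

**Phylogenetic turnover (βMNTD, βNTI).** For samples $j$ and $k$,

$$\beta\mathrm{MNTD}(j,k) = \tfrac12\Big[\sum_i w_{ij}\,
\min_{k' \in k} d(i,k') \;+\; \sum_i w_{ik}\, \min_{j' \in j} d(i,j')\Big]$$

where $d$ is the patristic distance between tips and $w_{ij}$ are
abundance weights: counts transformed by $\log(1+x)$ and renormalized over
the taxa present in the sample (absent taxa have weight zero). The null
model shuffles taxon identities across the tips — operationally, rows and
columns of the distance matrix are permuted while abundances stay fixed —
and βNTI is the z-score of the observed βMNTD against `n_randomizations`
such shuffles (1,000 for inference; smaller values are appropriate for
tests). One shared sequence of permutations is applied to every pair per
randomization, and all permutations are pre-generated from the seed, so
results are reproducible and independent of evaluation order.

Shared taxa contribute zero to both the observed and every null βMNTD
(a consistent relabelling keeps shared taxa shared), so βNTI is driven by
the *non-shared* taxa: when their nearest relatives in the partner
community are systematically closer than random relabelling predicts, the
pair converged under a common filter (βNTI < −2, homogeneous selection);
when they are farther, the pair was filtered apart (βNTI > 2, variable
selection). For this signal to exist at all, the observed taxon universe
must be phylogenetically broader than each community — a point that shaped
the synthetic scenarios below.

**Taxonomic turnover (abundance-based Raup–Crick).** For pairs not
dominated by selection, observed Bray–Curtis dissimilarity is compared
with a probabilistic re-assembly null: each sample is rebuilt from the
metacommunity preserving its observed richness and total reads — presence
drawn without replacement with probability proportional to occupancy
frequency, one read per drawn taxon, remaining reads multinomial with
probability proportional to metacommunity relative abundance. With
$n$ randomizations,

$$RC = 2\left(\frac{n_{\mathrm{null} < \mathrm{obs}} +
\tfrac12\, n_{\mathrm{null} = \mathrm{obs}}}{n} - \frac12\right) \in [-1, 1].$$

Ties are counted at weight 0.5 and detected at a $10^{-12}$ numerical
tolerance. One null community is assembled per sample per randomization
and all pairwise null dissimilarities are read off that null table, so the
whole matrix shares a single randomization stream. By default the
metacommunity is estimated from the analysis table itself (occupancy
counts and summed reads); `raup_crick_bray(metacommunity = ...)` accepts a
fixed external pool instead, which is how the package's own calibration
checks are run (see below) and how a user can restrict the null to a
host-specific pool.

**Classification.** Selection is evaluated first and RC never overrides
it: βNTI < −2 → homogeneous selection; βNTI > 2 → variable selection;
otherwise RC < −0.95 → homogeneous dispersal; RC > 0.95 → dispersal
limitation; |RC| ≤ 0.95 → undominated. Boundary values fall on the
non-selection / non-dispersal side (−2 ≤ βNTI ≤ 2 means selection does not
dominate the pair). Pairs whose βMNTD null is degenerate (zero standard
deviation, which happens when two samples share every taxon) are reported
as `NaN` with a warning, classified `"unclassified"`, excluded from
process fractions, and counted.

## Rarefaction replication and aggregation

Sequencing depth varies across samples, so the table is rarefied —
uniform subsampling without replacement — to a common depth, by default
19,600 reads, 100 independent replicate tables with per-replicate seeds
derived from one master seed. βNTI and RC are computed per replicate,
averaged per pair, and the *means* are classified once. Averaging before
classification avoids unstable majority votes for pairs whose indices sit
near a threshold; per-replicate labels remain available to a caller via
`pair_null_table()` if a vote is preferred. Replicates where a pair was
degenerate are dropped from that pair's mean and `n_replicates_used`
records the remainder.

Alpha diversity (bias-corrected Chao1 and root-inclusive Faith's PD) is
likewise computed per rarefied table and averaged; averaging is the
variance-minimizing aggregation and keeps the estimator at the common
depth. Faith's PD includes the stem path to the root, so the PD of a
single taxon is its root-to-tip depth and the PD of all taxa is the
tree's total branch length; `include_root = FALSE` gives the
crown-only convention.

## Group summaries and shifts

Pairs are labelled by the four host/site classes (`S.host&S.site`, …,
`D.host&D.site`). Process fractions within a group are computed over
classified pairs and sum to one; uncertainty comes from a percentile
bootstrap over pairs (1,000 resamples). Host- and site-induced shifts are
`fraction(different) − fraction(same)` per process, with percentile CIs
from the bootstrap deltas and a two-sided one-sample t test of the
bootstrap deltas against zero; the ten tests (5 processes × 2 contrasts)
are Benjamini–Hochberg adjusted as one family. Pairs sharing a sample are
not independent; bootstrapping pairs mirrors how the distance-based
quantities themselves are formed, and the CIs should be read accordingly.

Regression machinery (distance decay of similarity, latitude–diversity
gradients) bootstraps *samples*, not pair entries: each resample redraws
samples with replacement and rebuilds the pair set, excluding self-pairs
created by duplication. Slope CIs are percentile intervals of the
bootstrap slopes; the slope-difference test compares two bootstrap slope
vectors with an unpaired t test by default. (A paired option exists, but
the replicates of two independently bootstrapped regressions carry no
index pairing, and identical inputs would make a paired test degenerate.)
Similarity is 1 − Bray–Curtis throughout; the distance axis is linear km
(haversine on a 6371.0088 km sphere).

Core OTUs: a local core OTU at a site has within-site mean relative
abundance ≥ 0.1% and occurrence in at least ⌈80% × n⌉ of the site's n
samples (≥ 8 of 10 at the default design); a regional core OTU is a local
core OTU at every site sampled for that host. The abundance filter
applies to the site mean by default; `abundance_scope = "any_sample"`
gives the display-tree variant (threshold reached in at least one
sample). The "accounted for" coverage of a core set is the summed
per-sample-mean relative abundance of its members.

## The synthetic generator

The generator exists to make every stage of the pipeline testable with
known ground truth; it emulates the *processed* data a study of this
shape produces (count table, tree, metadata), not sequencing itself.

**Trees.** Real OTU phylogenies combine deep, well-separated backbone
lineages with shallow terminal radiations of closely related OTUs.
`sim_radiation_tree()` reproduces this: a Yule backbone with a small
coalescent radiation (default 3 tips at ~4% of backbone height) grafted
onto each lineage. This shape matters: the selection signal of βNTI lives
in the contrast between radiation-scale distances (a rare variant next to
its abundant sister) and backbone-scale distances (a random relabelling),
and on a plain Yule tree with tip-level communities the two scales are
not separated enough for any single-pool scenario to reach |βNTI| > 2.
`sim_tree()` (pure Yule) and `sim_traits()` (Brownian niche optima)
remain available as primitives.

**Selection scenarios.** A selected community is modelled as a
host-adapted *guild*: the 30 families nearest a random anchor lineage,
each contributing one dominant core OTU — core expected reads follow a
geometric rank-abundance profile — plus rare satellite variants pinned at
0.8 expected reads, so satellite presence is stochastic at the target
depth regardless of what that depth is. Samples are multinomial draws of
`depth` reads from this profile. `selection_strength` mixes the guild
with the neutral pool on a log10 scale (`0` recovers neutral sampling;
the default 6 is effectively pure guild assembly). The
homogeneous-selection scenario appends two unfiltered source-pool samples
("environmental source community"): without them the observed taxon
universe would coincide with the guild and the phylogenetic null would
have nothing to shuffle against — the same reason empirical βNTI analyses
are run on taxon tables pooled across habitats. Variable selection uses
two guilds anchored at maximally distant backbone lineages; each group
supplies the other's breadth, and within-group pairs carry a
homogeneous-selection truth.

An earlier design filtered a Brownian trait with a Gaussian kernel, as
one would write the model on paper. It fails quietly: Brownian optima
converge across distant clades, so the "selected" set is phylogenetically
scattered and βNTI stays near zero however strong the filter. The
clade-anchored guild keeps the conserved-niche assumption (the niche *is*
phylogeny-local) while making the selected set coherent; this is the
package's own design choice, documented here because the difference is
invisible in any single summary statistic yet decisive for the method.

**Dispersal scenarios.** Both dispersal scenarios build `n_pools`
isolated pools by neutral lineage sorting (each pool retains a random
fraction of ancestral lineages — 0.75 for homogeneous dispersal, 0.5 for
dispersal limitation) followed by Wright–Fisher drift (`depth`
individuals; 50 and 500 generations respectively). Samples are fully
mixed multinomial draws from their pool. Dispersal limitation is
diagnosed on between-pool pairs (divergence beyond the null);
homogeneous dispersal on within-pool pairs (far more similar than the
pooled-metacommunity null expects). Homogeneous dispersal is *only*
identifiable against a heterogeneous metacommunity — a pair drawn i.i.d.
from the metacommunity null itself is, by construction, RC-neutral — so
the scenario embeds the multi-pool background rather than a single shared
pool. The homogeneous-dispersal pools also keep a 5% per-generation
migrant trickle from the ancestral pool: it re-seeds rare lineages so the
marginal-presence band stays populated and within-pool pairs retain the
presence turnover a finite βNTI needs.

**Drift.** Each sample drifts independently from the ancestral pool for
30 Wright–Fisher generations with 10% migration back to it. The census
population is 10 × `depth`: gut census sizes exceed sequencing depth, and
with census equal to depth even a few generations of drift exceed
multinomial read noise, so the (sensitive) RC test reads pure drift as
dispersal limitation; with a very large census the drift perturbation
vanishes and the RC null's estimate-from-data bias (see the caveats
below) tips neutral pairs toward homogeneous dispersal instead. The
default sits between the two failure modes, and most pairs land in the
undominated band.

**The study-design bundle.** `sim_study_design()` composes these
mechanisms into the motivating layout: 2 host species × 5 sites × 10
replicates at 19,600 reads over a 274-tip radiation tree (the observed
union is somewhat smaller — a rare tail below detection is itself a
feature of real tables). One host assembles under guild selection — here
the guild's 30 lineages are spread across the whole phylogeny rather than
anchored to one region, because host specificity in the bundle must be
taxonomic, not phylogenetic: a backbone-clustered flora makes the
*other* host's turnover look phylogenetically structured and tips
between-host pairs from dispersal limitation into variable selection —
plus a shared set of ~60 resident generalists, one per evenly spaced
lineage, carried by both hosts (they bridge the floras phylogenetically
for the same reason). The other host's samples drift around site
pools that themselves drift along the latitudinal chain, producing
distance decay of similarity. MAT and MAP decrease monotonically with
latitude in the metadata. The pair-class truth is: within selected host —
homogeneous selection; within drifting host — undominated (empirically a
mix of undominated and homogeneous dispersal once the pooled two-host
metacommunity is the null's reference, which mirrors how within-host
cohesion is read in real two-host data sets); between hosts — dispersal
limitation.

## Numerical and interface choices

* Counts must be integers; floating-point tables are rejected rather than
  rounded, because rarefaction subsamples discrete reads.
* The log transform is applied to counts first, then weights are
  renormalized over present taxa (`abundance_weights()`); natural log with
  a +1 offset.
* Tip-shuffle permutations and bootstrap resamples are pre-generated from
  the seed; per-replicate and per-group child seeds are derived from the
  master seed, so any subset of the computation is reproducible in
  isolation and results are bit-identical to serial evaluation.
* Mantel and partial Mantel tests delegate to vegan with the +1
  permutation correction, 999 permutations by default.
* Degenerate cases are explicit: zero-variance bootstrap distributions
  report boundary p-values with a flag; empty groups are omitted with a
  warning; all-zero samples are an input error.
* Test and example problem sizes (200 taxa, 20 samples, 2,000 reads,
  200 randomizations; 2 rarefied replicates in the end-to-end example)
  were chosen so a full scenario analysis runs in seconds-to-minutes;
  inference-grade settings are the defaults on the analysis functions
  themselves (1,000 randomizations, 100 replicates).

## What passing tests do and do not show

The synthetic scenarios are built so that each process is *cleanly*
detectable: guild structure is sharp, pools are well separated, and noise
sources not in the model (chimeras, contamination, compositional
artefacts, copy-number variation, time dynamics) are absent. Recovery
rates near 100% on these scenarios validate the machinery — the indices,
nulls, thresholds, aggregation and bootstrap — not the expected power on
real data, where processes mix within pair classes and effect sizes are
smaller. Conversely, the calibration checks (samples drawn i.i.d. from
the RC null's own generative model score |mean RC| < 0.1 and |mean βNTI|
< 0.5) guard against the opposite failure, a machinery that manufactures
signal from nothing. Two caveats deserve emphasis: the RC null's
metacommunity is estimated from the analysis table, and applying the test
to data generated from a *known* pool while letting it re-estimate that
pool produces visibly negative RC — calibration must supply the
generative metacommunity, and users comparing nested sample sets should
fix the pool explicitly; and βNTI has no signal when communities saturate
the observed taxon universe (rich pairs sharing every taxon are reported
degenerate rather than silently zero).
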