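---
title: "Methods: multi-strain phenotyping, pan-genomics and strain-specific metabolic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-strain phenotyping, pan-genomics and strain-specific metabolic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pangem)
```

pangem implements a complete multi-strain systems-biology workflow for a
bacterial species panel: kinetic phenotype calling, pan-genome and alleleome
construction, and derivation plus phenotype-driven refinement of
strain-specific genome-scale metabolic models (GEMs) from a pan-model. This
vignette is the package's account of the underlying methods: the models and
their assumptions, the tunable parameters, what the synthetic-data generator
does and does not emulate, and the numerical and design choices that were
genuinely open.

## Growth calling from kinetic traces

Phenotype-microarray instruments report a respiration signal per well over
time (tetrazolium-dye reduction in arbitrary units). The calling procedure
is:

1. **Smoothing.** Each trace is smoothed with a Savitzky–Golay filter,
   window length 50 and polynomial degree 3. Classical SG filters require an
   odd window, so a requested even window is rounded *up* to the next odd
   value (51) and the adjustment is reported; this preserves the intended
   smoothing scale. SG filters reproduce polynomials up to the filter degree
   exactly, so flat baselines are untouched.
2. **Feature extraction.** The maximum smoothed signal over the full time
   course is the well's statistic. No other curve features (AUC, lag) are
   used.
3. **Testing.** The blank (negative-control) wells of each plate run form a
   control group; their maxima give a mean $\mu$ and sample ($n-1$) standard
   deviation $\sigma$. Each substrate well is tested one-sided:
   $z = (\max - \mu)/\sigma$, $p = 1 - \Phi(z)$.
4. **Correction.** Bonferroni over the number of substrate wells tested on
   that plate: $p_{adj} = \min(1, m\,p)$. A well shows growth when
   $p_{adj} < \alpha$ (strictly; a tie at $\alpha$ is no-growth), with
   $\alpha = 0.05$.
5. **Replicates.** A (strain, substrate) cell is called growth only if it is
   significant in *every* replicate plate (conservative AND rule; a majority
   rule is available). The reported per-cell p-value is the order statistic
   that decides the call, so `call == (p_adj < alpha)` holds by
   construction.

**Control pooling.** Each plate run forms its own control group
(`control_pooling = "replicate"`), mirroring per-plate processing; pooling
across a strain's replicates is available as an option. This choice matters
statistically: the max-of-a-smoothed-series statistic is right-skewed, so
the nominal z-test is anti-conservative per well. When every replicate has
an independent control group, the AND rule compounds the per-replicate error
rates and the family-wise false-call rate stays below $\alpha$ (the
acceptance suite measures it empirically over simulated all-null plates).
If controls are instead pooled across replicates, the $\hat\sigma$ error is
shared between replicates, the AND rule no longer compounds, and the
family-wise rate can exceed $\alpha$. The per-replicate default is therefore
both the more faithful reading of per-plate processing and the
statistically sound one.

Degenerate controls ($\sigma = 0$, possible only with noiseless synthetic
data) raise an error by default; an explicit `sigma_floor = TRUE` substitutes
$10^{-6}|\mu|$.

**Compound groups.** Calls are summarized per compound group (the eight
structural groups of the 190 microarray substrates — organic acids 41,
L-amino acids 21, monosaccharides 17, oligosaccharides 24, sugar acids and
alcohols 26, modified sugars 26, aromatics 7, others 28; see
`biolog_compound_groups()`). A strain's activity on a group is the fraction
of its substrates called growth; the group's *metabolic activity index* is
the mean of that fraction over strains. `assay_agreement()` compares two
call matrices (e.g. respiration-based vs colony-based assays) on their
overlapping cells and tallies the discordance directions.

## Pan-genome construction

Gene families are built by greedy incremental identity clustering — the
published strategy of CD-HIT-style tools, re-implemented at desk scale with
full global alignment instead of k-mer prefiltering:

* records sorted by decreasing length (ties lexicographic by strain, gene);
* each record joins the first existing family whose representative it
  matches at `identity >= 0.9` (CD-HIT's default threshold), where identity
  is matches / alignment columns of a global BLOSUM62 alignment with a
  linear gap penalty of 8 per residue;
* otherwise it founds a new family and becomes its representative.

A sound length-ratio prefilter (identity can never exceed
min(len)/max(len)) skips alignments that cannot reach the threshold.
Determinism follows from the stated sort and tie rules. We do not attempt to
reproduce any specific tool's exact cluster boundaries or word-filter
heuristics.

The strain × family **presence matrix** (paralogs count once) feeds three
summaries: the **ordered core-genome curve** (strains sorted by shared-family
count, most-shared first, ties lexicographic; the k-th value is the family
intersection of the first k strains — non-increasing by construction, with
an ordering-invariant endpoint), **strain blocks** (average-linkage
hierarchical clustering on Jaccard distance between presence rows, cut to
`n_blocks`, labelled in order of first appearance along the lexicographic
strain order), and the alleleome below. Jaccard + average linkage is a
choice — the upstream literature names only "a hierarchical clustering
method" — and is recorded in the output metadata.

## Alleleome

An **allele** is a unique amino-acid sequence within a family; its frequency
is the number of distinct strains carrying it. A strain carrying two
*distinct* paralogous sequences contributes to both alleles; identical
copies count once. Alleles are ranked by strain count (ties by lexicographic
sequence) and named after their strain count, with `count-1`, `count-2`, …
suffixes when several alleles share a count. **Dominant** alleles are those
in strictly more than 50% of strains.

Substitutions relative to the dominant allele are classified conservative
when both residues share a physico-chemical group
({AVLIMC}, {FWY}, {ST}, {NQ}, {DE}, {KRH}, {G}, {P}); the grouping is a
standard hydrophobic/aromatic/polar/charge partition, stated here because no
single canonical grouping exists. Unequal-length alleles are globally
aligned to the dominant allele first, and gapped columns are tallied
separately as indels.

**Clade splits.** Allele sets (≥ 3 alleles) get a neighbor-joining tree on
p-distance (fraction of differing aligned positions; branch lengths in
substitutions per site), midpoint-rooted; the root's two subtrees define the
major (more alleles; ties by total strain count) and minor clades.
NJ + midpoint replaces maximum-likelihood tree inference deliberately: it is
deterministic, dependency-light, exact on additive distances (the test suite
verifies recovery of 5-leaf additive matrices against exhaustive topology
search), and sufficient for a two-clade assignment. Bootstrap support is out
of scope. One caveat the test suite documents: for a *perfectly symmetric*
star alleleome (dominant equidistant from k singletons), NJ attaches the
central dominant allele as a cherry with one singleton, and midpoint rooting
can leave that cherry as the minor clade — a degenerate configuration where
"the dominant allele sits in the major clade" fails by symmetry.

## Metabolic networks, FBA, and strain models

The network container is the standard constraint-based shape: metabolites
with compartments (c/p/e), reactions with bounds (mmol/h/gCDW), sparse
stoichiometry, boolean gene–protein–reaction (GPR) rules, and one biomass
objective; COBRA-style JSON I/O round-trips ids, bounds, GPR strings and
subsystem labels. GPRs are parsed to an AST at load time (malformed rules
fail at construction, never mid-simulation); the empty rule is always true
(non-genetic reactions survive every pruning).

**FBA.** Growth is the linear program
$\max_v c^\top v$ s.t. $Sv = 0$, $lb \le v \le ub$. For a growth test on
substrate $c$, all carbon exchanges are closed, the exchange of interest is
opened at an uptake of 10 mmol/h/gCDW, and `medium` exchanges (inorganics in
a real model) stay open. Growth is declared when the optimal objective
exceeds $10^{-6}$/h — the tolerance is configurable and logged, since
"capable of growth" is otherwise undefined. The LP is solved by an
in-package dense two-phase primal simplex with Bland's anti-cycling rule:
no LP library ships with this package's dependency set, and the instances
here are tiny (tens of variables), where a dense exact method is simpler and
more transparent than an external solver. The test suite checks it against
hand-solved mass-balance optima, an independent simplex implementation on
small instances, and permutation/scaling invariances. Only the objective
value is contract-bearing; alternative optimal flux vectors are acceptable.

**Orthology and pruning.** Strain models derive from the pan-model by
bidirectional best hits (BBH): exact global-alignment percent identity
(BLOSUM62, linear gaps, identity = matches/columns — a documented deviation
from BLAST's local identity), mutual-best pairing with lexicographic tie
breaks, and a 60% identity cutoff. Pan genes without a partner are removed,
GPRs are re-evaluated mechanically over the survivors (no manual rescue of
partially satisfied AND rules), reactions whose rule turns false are
dropped, and orphan metabolites are pruned. Provenance (removed genes and
reactions, later gap-fills) travels with each model; derived models are
always sub-networks of the pan-model.

**Gap-filling** is uniform-cost minimum-cardinality: the smallest set of
universal-network reactions whose addition restores growth on the target
substrate, found by exhaustive search over candidate subsets of increasing
size with lexicographic tie-breaking (the candidate sets that arise from
GPR pruning are small; the suite verifies minimality against full subset
enumeration on every instance with ≤ 12 candidates). A model that already
grows returns the empty set; if no subset helps, an explicit infeasibility
is reported rather than a padded model. The pipeline gap-fills twice: first
for viability on glucose (every strain must grow on the reference carbon
source), then phenotype-driven — for every observed-growth cell the model
misses, a minimal fill on that substrate is attempted.

**Validation and classification.** Predicted growth matrices (substrate
lacking an exchange in a strain model ⇒ predicted no-growth, a model
statement rather than an error) are scored against observed calls: accuracy,
false-positive and false-negative rates over the overlapping cells, with
per-substrate error tallies for triage. Reactions are classified across
strain models by frequency: core ≥ 0.98, rare < 0.10, accessory in between
(the published class wording overlaps at its boundaries; this
left-closed convention at 0.98 and right-open at 0.10 makes the classes a
partition). Multiple correspondence analysis uses the indicator-matrix
formulation — two categories per reaction, empty categories dropped — via
SVD of the standardized residual matrix; strain principal coordinates and
principal-inertia fractions are returned, and the suite checks the
coordinates against an independent eigen-decomposition route to 1e-10.

## The synthetic world

Real inputs for a study of this kind are genome assemblies, kinetic plates,
and agar assays. The generator emulates their statistical structure with
full ground truth, so every stage is testable without downloads:

* **Gene repertoires.** Core families in every strain; accessory families
  present independently with probability 0.6; rare families in exactly one
  strain. Defaults: 8 strains, 20 core + 15 accessory + 4 rare families.
* **Alleles.** Each family has a random reference protein (150–400
  residues, typical bacterial sizes); each strain's copy receives binomial
  point substitutions at 0.02 per site (uniform over the 19 alternatives, or
  within-group for stress tests; single-residue indels behind an explicit
  switch). At these lengths two alleles of a family differ by ~4% of sites,
  far inside the 0.9 clustering threshold, so family recovery is
  statistically stable rather than seed-lucky.
* **Metabolism.** A toy universal network: one linear catabolic pathway per
  substrate (2–3 reactions) from a substrate exchange to a common biomass
  precursor, plus a biomass sink. Pathway 1 ("glc") is gated by core
  families — every strain grows on glucose; each remaining pathway reaction
  is gated by its own accessory family, so losing one family breaks exactly
  one substrate and truth recovery is interpretable. Configurations that
  would need more gating families than exist are rejected at construction.
* **Phenotypes.** True growth = FBA on the strain-restricted network;
  self-consistency with the gating rules is asserted at generation time.
* **Plates.** 48-hour traces read every 30 minutes (97 points, comfortably
  above the 51-point smoothing window), three replicate plates per strain,
  three blank wells per plate; growers follow a logistic normalized to start
  exactly at the baseline (10) and plateau exactly at the amplitude (200) at
  the final read, non-growers stay at baseline, both plus i.i.d. Gaussian
  noise (sd 5). Gaussian noise is an assumption of the generator, not a
  claim about any instrument's error family.
* **Reproducibility.** One root seed; every stage draws from a named child
  stream (`genomes`, `proteins`, `alleles`, `network`, `plates`), so adding
  a stage never perturbs another's draws, and a fixed seed reproduces the
  world exactly.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: assembly and annotation artifacts, paralog
inflation, horizontal transfer, operon structure, correlated or
heteroscedastic plate noise, redox-positive-but-no-growth substrates (the
known divergence between respiration- and colony-based assays), and the
scale of real panels (hundreds of strains, thousands of reactions).
Published whole-panel statistics — core-genome sizes, family counts, real
accuracy percentages, allele-length averages — depend on the real strain
panel and are deliberately not targets here; the suite instead verifies the
properties that make those statistics computable (exact bookkeeping
arithmetic, error-rate control, oracle-checked optimization and
ordination).

## Problem sizes and run times

The default world (8 strains × 6 substrates, ~39 carried families, a
24-reaction universal network) keeps a full pipeline run — clustering,
BBH, model derivation, two gap-fill passes, classification, MCA — in the
tens of seconds. The statistical checks use 1,000 simulated all-null
strain-plates for the family-wise error rate and 200 mixed plates for power
in the test suite (600 and 150 in the acceptance script); these sizes give
two-digit binomial precision on the measured rates. All of these are the
package's own choices of experiment size and can be scaled up through the
configuration objects.

## Known limitations

* The greedy clusterer is quadratic in the number of families per length
  class; it is meant for panel-scale protein sets, not metagenomes.
* The simplex solver is dense and unsuited to genome-scale LPs with
  thousands of reactions; swap in a sparse LP backend before applying the
  FBA layer to full-size reconstructions.
* Exhaustive gap-fill search is exponential in the candidate count and
  capped (default 4 additions); large universal networks need the weighted
  MILP formulation instead.
* The z-test inherits the anti-conservativity of testing an extreme-value
  statistic with a normal tail; the per-replicate control design contains
  it, but single-replicate designs with few controls will over-call growth.
* Midpoint rooting is ambiguous on perfectly symmetric distance
  configurations (see the star-alleleome caveat above).
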