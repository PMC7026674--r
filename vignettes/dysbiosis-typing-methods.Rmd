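---
title: "Methods: dysbiosis typing and hierarchical classification of gut microbiota"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dysbiosis typing and hierarchical classification of gut microbiota}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dysbiotyper)
```

# Overview

`dysbiotyper` implements an analysis pattern common in hospital microbiome
studies: stool communities of hospitalized gastroenterological patients and
non-hospitalized controls are (i) typed into community states by
unsupervised clustering of Bray-Curtis dissimilarities, (ii) characterized
by diversity, differential abundance and clinical covariates, and (iii) fed
into a hierarchical classifier that asks how much information the microbial
community carries about diagnosis-based patient groups beyond ordinary host
factors (age, gender, antibiotic exposure).

The package ships a synthetic-cohort generator so the whole pipeline runs,
and is tested, without any external data. This vignette documents the
models, the tunable parameters, the numerical choices and the limits of
what the synthetic experiments can show.

# The synthetic cohort

`cohort_config()` / `generate_cohort()` emulate a cohort of 121 hospitalized
patients — five diagnosis groups: Crohn's disease (15), ulcerative colitis
(25), infection (23), tumor (22), other (36) — plus 162 healthy controls.
Group sizes, age distributions, gender and antibiotic-exposure rates follow
the host-factor table of the study design the package mirrors.

Each subject carries a latent community state:

* **C1** — healthy-like; all controls and roughly half of the patients;
* **C2** — *Enterobacteriaceae*-enriched (*Escherichia/Shigella* and other
  *Enterobacteriaceae* up ~50-70x on the log scale used, commensal
  *Clostridiales* depleted);
* **C3** — *Enterococcus*-enriched (*Enterococcus* up ~e^6, *Streptococcus*
  up, strong commensal depletion).

State assignment depends on antibiotic exposure (probabilities 0.35/0.45/0.20
with antibiotics vs 0.75/0.23/0.02 without), producing the antibiotic
gradient across clusters seen in practice (controls ~6%, C2 ~50%, C3 >90%).

Counts are Dirichlet-multinomial: the state's log-fold-change vector is
added to the log base profile, renormalized (so compositions stay valid for
any effect size), used as the mean of a Dirichlet with concentration
`overdispersion` (default 50, giving inter-individual Bray-Curtis spreads
comparable to real 16S data), and a multinomial draw at a uniform random
depth (3,000-10,000 bacterial reads, 900-4,000 fungal reads; the fungal
floor deliberately leaves a few percent of samples below the 1,000-read
rarefaction depth so the dropping path is exercised).

Inflammation markers exist only for hospitalized subjects (controls are
missing-coded, as in retrospective chart review). CRP is linear in
*Enterococcus* relative abundance — intercept 15 mg/L, slope 34 mg/L per
unit relative abundance, Gaussian noise sd 12.5 mg/L, truncated at 0. The
slope was solved analytically from `r = s/sqrt(s^2 + sd^2)` with the
empirical spread of *Enterococcus* across patients so that the sample
correlation at n = 121 recovers the configured target r = 0.463.
Leukocytes and neutrophils are baseline (7 and 4.5 x 10^9/L) plus a shift
(+5, +4) for C3 subjects.

**Calibration note.** Effect magnitudes are not published quantities; they
were calibrated once so that the generated cohort actually exhibits the
study conditions the pipeline is meant to recover: three clusters whose
silhouette-optimal k is 3 (an earlier, weaker calibration produced a k = 3
cost optimum that preferred splitting the large heterogeneous C1 over
isolating the ~10-subject C3 — the reference `cluster::pam` behaved
identically — so k = 2 won the silhouette scan), differential-abundance
scores for the defining taxa in the 4-6 range on per-million scaling, and a
positive bacterial information gain for the hospitalized/control split.

Randomness is split per subject: subject *i* always draws from a substream
derived from `(seed, i)`, so enlarging a cohort never changes earlier
subjects' data.

**What the generator does not emulate:** read-level error and chimeras,
phylogenetic correlation between taxa, compositional interactions beyond
closure, longitudinal structure, and any true dependence of the community
on age or gender. Passing recovery tests on this cohort therefore shows the
estimators work when their assumptions hold, not that the biological
effect sizes of any real cohort are attainable.

# Preprocessing

Order is fixed: subject exclusion, rare-OTU filtering, rarefaction.

* `exclude_subjects()` applies rules first-match, so the per-rule exclusion
  counts are disjoint and sum to the number removed.
* `filter_rare_otus()` removes OTUs whose dataset-wide relative abundance is
  strictly below 0.01% (an OTU exactly at the threshold is kept). The
  threshold is interpreted against the pooled dataset, not per sample.
* `rarefy()` subsamples each sample's reads without replacement (mothur
  convention; the count variance test against hypergeometric moments would
  fail for a with-replacement scheme) to a fixed depth, defaults 3,000
  bacterial / 1,000 fungal reads, dropping and logging shallower samples.

# Community statistics

Shannon diversity is in natural log. Bray-Curtis dissimilarities come from
`vegan::vegdist()`. The distance-based AMOVA partitions pairwise squared
distances among vs within groups (the form used by mothur, not the
haplotype-frequency AMOVA of population genetics) with an F-like ratio and
a label-permutation p-value; all permutation p-values use the +1 correction
and are never exactly 0. `permanova()` delegates to `vegan::adonis2()` with
sequential (order-as-given) terms and free permutation of observations —
the joint explained variance reported for, e.g., age + antibiotics is the
sum of the sequential term R². The dispersion test measures each sample's
distance to its group *medoid* — this stays in distance space and is a
deliberate approximation to the centroid-based test; for strongly
non-Euclidean dissimilarities the two can differ.

# Dysbiosis typing (PAM + silhouettes)

`pam_cluster()` minimizes the sum of distances of samples to their cluster
medoid. Two deterministic paths share that objective:

* when the number of candidate medoid sets `choose(N, k)` is at most
  `exact_limit` (default 10,000), the optimal set is found by exhaustive
  enumeration;
* otherwise the classic greedy BUILD seeding plus steepest-descent SWAP is
  used, stopping when no single medoid exchange lowers the cost.

The hybrid exists because BUILD+SWAP is a local search: on small random
dissimilarity matrices it (like the reference `cluster::pam`) misses the
global optimum in roughly 7-13% of instances. Exact enumeration where it is
affordable makes the small-instance behavior match the method's contract
exactly, while cohort-scale problems (e.g. 283 samples) use the heuristic.
Both paths are seed-free; ties break by input order.

Silhouette widths follow the usual `(b - a)/max(a, b)` definition with
singleton clusters scored 0 (the R `cluster` convention). `select_k()`
scans k = 2..10 by default and takes the highest mean silhouette, ties to
the smaller k. A maximum mean silhouette below 0.3 is flagged as weak
structure by the pipeline, and cluster contrasts downstream should then be
read as exploratory.

For reporting, the pipeline relabels clusters by decreasing size and splits
the largest (C1) by hospitalization status into C1(NHC)/C1(HP), mirroring
how mixed healthy/patient clusters are usually presented.

# Differential abundance (LEfSe-style)

`lefse()` is a reimplementation of the two-stage effect-size idea, not a
bit-compatible port of the original tool: a Kruskal-Wallis screen at
`alpha = 0.05` per feature, then a bootstrapped linear-discriminant effect
size for survivors. The subclass (pairwise Wilcoxon) stage of the original
is omitted because this pipeline defines no subclasses. Per bootstrap round
(30 rounds, 2/3 of each class subsampled without replacement), a Fisher
discriminant is fitted on all surviving features jointly with a ridge
`1e-6 x mean feature variance` guarding singular covariances; the
per-feature effect is the mean of (a) the between-class displacement along
the unit discriminant attributed to that feature and (b) the raw class-mean
difference, both in per-million abundance units. The final score is
`log10(1 + mean |effect|)` — the `1 +` keeps the zero-effect score finite
at 0. With more than two classes each class is scored one-vs-rest and the
feature keeps its maximum. A feature "passes" when it clears both the
screen and the score cutoff (default 2.0).

Scores on per-million scaling land in the 3-6 range for strong effects;
published per-dataset scores are a plausibility range for the synthetic
cohort, never an exact target. Note one subtlety used by the tests: when a
single feature truly shifts in compositional data, closure makes all other
features differential too — size control is only meaningful on fully
exchangeable data.

# Hierarchical classification (PCT forests)

Diagnosis groups form a tree: `Subject -> {NHC, HP}`,
`HP -> {IBD, Infection, Tumor, Other}`, `IBD -> {CD, UC}`. Every sample's
label is the full root-to-leaf path (a 0/1 vector over the 9 nodes), and
every prediction is a probability vector that automatically satisfies
`child <= parent` because leaf prototypes do and averaging preserves it.

A predictive clustering tree greedily chooses splits maximizing the
reduction of within-node variance of label vectors under the weighted
squared Euclidean distance with node weights `w0^depth` (default
`w0 = 0.75`, the customary default of the PCT literature; exposed as a
parameter). Thresholds are midpoints between consecutive distinct feature
values; ties go to the lowest feature index, then the lowest threshold.

**Stopping rule.** Growth stops at label homogeneity, at fewer than
`2 x min_leaf` samples (default `min_leaf = 2`), or when no split respects
`min_leaf`. A split with *zero* variance reduction on an impure node is
accepted: strictly requiring positive reduction would make conjunctive
patterns such as XOR unlearnable (every single split of XOR labels has
exactly zero reduction), and growing to the size limit is the standard
Random Forest convention, which rarely pre-prunes. The F-test pre-pruning
of the original PCT system is intentionally not used.

Forests train 100 trees by default, each on a bootstrap sample with
`mtry = ceiling(sqrt(p))` random candidate features per node; out-of-bag
indices are recorded per tree. Genie3 importance accumulates
`n_samples x variance_reduction` over every split using a feature, averaged
over trees; unused features score exactly 0 and the scores sum to the mean
per-tree total reduction (a conservation property the tests assert).

# Evaluation

Per-node precision-recall curves enumerate one point per distinct score
threshold (positive iff score >= threshold). AUPRC integrates the curve by
trapezoids over achievable points, left-anchored at (0, precision of the
first point); PR interpolation is nonlinear in general, so the tests
cross-check against a dense-threshold numeric oracle rather than a closed
form. The pooled "AUPRC-bar" micro-averages TP/FP over all non-root nodes
(the root is always positive and therefore excluded), which is equivalent
to computing a single PR curve on the concatenated (score, truth) pairs.

The default protocol is out-of-bag — each sample is scored only by trees
whose bootstrap excluded it, the natural choice for bagged ensembles —
with stratified k-fold cross-validation available; which protocol produced
any published figure is generally unknowable, and on stable synthetic data
the two agree within ±0.1 here. Nodes with zero positives are reported as
absent, not as 0.

ΔAUPRC is the node-wise difference between a microbial feature set
(host + bacteria, host + fungi, host + both) and the host-only baseline,
computed on the identical sample set and protocol. On the synthetic cohort
the pipeline reproduces the *direction* of the published contrasts
(bacteria informative for the hospitalized/control split, fungal gains
smaller, occasional small negative deltas for noise-dominated nodes);
the magnitudes are dataset-bound and not comparable.

# Problem sizes used by the test-suite and acceptance script

The packaged experiments run the full 283-subject default cohort for the
headline run and the 20-seed recovery checks (k = 3 selection, positive
HP delta for bacteria, CRP correlation), 100-tree forests for the two
feature sets in the recovery loop, 200 simulations per permutation test for
size control, 200 random small instances for the PAM oracle, 500 instances
for the split oracle, and 1,000 random inputs for the
hierarchy-consistency invariant. These sizes were chosen to keep the
statistical checks well-powered while the whole suite completes in a few
minutes on one CPU.

# Known limitations

* The PCT forest handles tree-shaped hierarchies only (no DAGs) and numeric
  features only; binary host factors are 0/1-encoded, missing features are
  mean-imputed with training means.
* The dispersion test's medoid formulation is an approximation of the
  centroid-based dispersion test.
* LEfSe-style scores are not comparable to the original tool's numbers at
  the decimal level (different discriminant regularization, no subclass
  stage).
* PAM's heuristic path is a local search; only the exact path guarantees
  the optimal medoid set.
* The generator draws each taxon independently within the Dirichlet, so
  co-occurrence structure beyond compositional closure is absent; Genie3
  rankings on synthetic data are easier than on real, correlated
  communities.
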