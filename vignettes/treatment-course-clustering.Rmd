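---
title: "Clustering treatment courses: model, design choices, and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering treatment courses: model, design choices, and what the tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treatclust)
```

## The problem and the model

Clinical cancer registries record, for each patient, a *treatment course*:
the diagnosis followed by the surgeries, radiotherapies and systemic
therapies that were reported for the case. treatclust groups breast-cancer
patients by the similarity of these courses, so that registry staff can
review coherent groups of courses, find unexpected care patterns, spot
data-quality problems (e.g. radiotherapy reported before the
breast-conserving surgery it should follow), and compare survival between
groups of similar courses.

The similarity measure has two levels.

**Event level.** Each event type is compared through a weighted average of
attribute distances, all normalized to $[0,1]$:

* *Diagnosis*: UICC stage (ordinal $0\ldots4$), ECOG performance score
  (ordinal $0\ldots4$), age band relative to screening eligibility
  (categorical: under 50 / 50--69 / over 69), histology (categorical over
  six comparable morphology codes), and a differentiation scale for
  grading (ordinal $0\ldots8$), all weighted $0.2$. Ordinal attributes use
  the range-normalized distance $|a-b|/\mathrm{range}$; categorical
  attributes are $0/1$.
* *Surgery*: procedure group ($0.5$), residual status R0/R1(is),R1(cy+)/R1/R2
  mapped to $0,1,2,3$ ($0.25$), and the Jaccard distance between
  complication-code sets ($0.25$). OPS procedure codes are grouped into
  breast-conserving surgery (prefix 5-870), mastectomy (5-872/5-874/5-877)
  and other breast surgery (5-879); codes outside these families are
  ignored, and a surgery matching no group or several groups gets an
  *unrelated* group value.
* *Radiotherapy*: aggregated target region ($0.5$; identical regions $0$,
  breast vs. thorax $0.5$), Jaccard distance of the pooled application
  types ($0.25$), and the temporal relation to the primary surgery
  (adjuvant / neoadjuvant / intraoperative / unrelated, $0/1$; $0.25$).
* *Systemic therapy*: an expert-derived $14\times14$ distance matrix over
  the therapy-type codes (CH, HO, ..., OT, plus MI for a missing type)
  weighted $0.7$, and the temporal relation weighted $0.3$.

Missing values (undocumented) and unrelated values (documented but outside
the comparable value set) are never dropped. Both take the maximum
distance 1 from every value *including themselves*: two patients whose
stage is unknown are not treated as similar just because the same field is
empty. A consequence worth knowing: an event with missing attributes has a
positive distance from itself, each such attribute contributing exactly its
weight. Events of different types are incomparable and have distance 1.

**Course level.** Courses are date-ordered event sequences (ties broken
diagnosis < surgery < radiotherapy < systemic, then input order; undated
events sort last). The distance between two courses is a modified
Levenshtein distance: insertions and deletions cost 1, a substitution
costs the event-level distance, and the dynamic-program total is divided
by the length of the longer sequence, so short and long courses remain
comparable. Two empty courses have distance 0; any nonempty course is at
distance 1 from the empty course. The diagnosis participates as the first
event of the sequence.

The pairwise matrix over a cohort is computed in compiled code
(`pairwise_matrix()`), with the single-pair pure-R `course_distance()`
kept as an independently testable reference. The matrix diagonal is
forced to zero - the embedding requires a genuine zero diagonal - while the
semantic self-distance of an incomplete course remains available through
`course_distance(x, x)`.

## Embedding and cluster-model selection

The distance matrix is embedded in the plane before clustering, both for
separability and because the whole review workflow (scatter plots, cluster
legends) lives in 2D. The default embedding is classical (metric)
multidimensional scaling (`stats::cmdscale`), a deterministic spectral
method. Non-metric MDS (`vegan::monoMDS`, started from the classical
solution) is available via `embedding_config(method = "nmds")`.

This was a genuinely open design point. We compared both on synthetic
cohorts with planted archetypes: non-metric MDS, which fits only the rank
order of the dissimilarities, reproduces the one dominant gap in the
course metric (short courses vs. long courses) and compresses adjacent
archetype groups until silhouette-based model selection prefers a
two-cluster solution; classical MDS spreads the archetype groups evenly
enough that the selected clustering recovers the planted structure
(adjusted Rand index $\ge 0.9$ at $n = 1000$, see the acceptance tests).
We therefore ship classical MDS as the default. Embedding coordinates are
deterministic given the input matrix; the configured seed is recorded with
every persisted embedding for provenance.

Three clustering algorithms run on the embedded points over a parameter
grid:

* complete-linkage agglomerative clustering, cut at a log-spaced
  `distance_threshold` grid ($0.1$ to $30$, 25 values);
* DBSCAN over `eps` ($0.05$ to $2.0$, 20 values) $\times$ `min_samples`
  $\{5,7,10,15,25\}$;
* a hierarchical density method (HDBSCAN-style: mutual-reachability
  single linkage, condensed by a minimum cluster size, flat clusters by
  excess-of-mass stability) over `min_cluster_size`
  $\{10,25,50,100,200\}$ $\times$ `min_samples` $\{5,10,25\}$.

The grids are defaults, not dogma (`default_grids()` is replaceable); they
bracket the coordinate scale classical MDS produces for distances in
$[0,1]$. A configuration is admissible if its cluster count lies in the
requested granularity band - coarse (1--50), medium (51--100), fine
(101--200), or a custom band such as the 15--30 used for survival
comparisons - and if at most 5% of courses are outliers. Among admissible
configurations the mean silhouette width decides, computed on the 2D
embedding with Euclidean distance (outliers excluded, singleton clusters
scoring 0); a switch allows scoring on the original course distances
instead. Ties break lexicographically by algorithm name and parameter
string, and an unsatisfiable band is reported as such rather than raised
as an error.

Each cluster is characterized by its medoid (the member with the smallest
distance sum; ties to the smallest id), the five courses most and least
similar to the medoid, attribute frequency tables, and two SVG views: the
labelled scatter of the embedding and per-cluster sequence diagrams (one
row per course, one cell per event, colored by the event's
highest-weighted attribute: UICC stage, surgery group, target region, or
therapy type). The SVG is written directly by the package so that
identical inputs produce byte-identical files.

## Intercluster survival analysis

The survival workflow asks whether clusters formed *without any survival
information* still differ in survival. To keep prognostic case-mix from
driving the answer, the cohort is first restricted: ages 50--69 at
diagnosis, survival of at least the 56-day landmark period, documented
grading, and either the prognostically favorable subgroup (UICC I--II) or
the unfavorable one (UICC III--IV). Each filter's attrition is reported.

Per cluster, survival from the landmark origin (diagnosis + 56 days) is
estimated by the Kaplan-Meier product-limit estimator with right
censoring at the registry's last mortality linkage (2023-06-30 by
default), with complementary log-log Greenwood confidence intervals - the
source material names no interval method, so we chose the transform that
respects the $[0,1]$ range. The 4-year survival is read at $t = 1460$
days (4 years at 365 days; no day convention was stated). Clusters with
no deaths are flagged and excluded from model-based comparison - their
hazard is not estimable - but never silently dropped.

A Cox proportional-hazards model (`survival::coxph`) then adjusts the
intercluster comparison for age (linear), grading (categorical, reference
G1), UICC substage (categorical; reference IA in the favorable subgroup,
IIIA in the unfavorable one, i.e. the first level present) and lobular
vs. non-lobular histology. The reference cluster is the one with the
highest observed 4-year Kaplan-Meier survival (ties: larger cluster, then
smaller label). The DBSCAN outlier label $-1$ participates as a cluster
level of its own. Gender is not part of the default adjustment; any extra
column of the records can be added through `extra_terms`.

Adjusted survival curves come from G-computation: for each cluster $c$,
every patient's cluster is counterfactually set to $c$, the fitted model
predicts each patient's curve, and the curves are averaged. Predictions
use the model's estimated baseline hazard via `survival::survfit` on the
fitted model (`stype = 2`, the exponentiated cumulative-hazard form, by
default; `stype = 1` selects the product-limit form, under which a
strata-only model reproduces the stratified Kaplan-Meier exactly - the
property the test suite exploits). The time grid defaults to the observed
event times and is truncated at the longest observed follow-up.

## The synthetic registry generator

No real registry extract ships with the package; the generator is the test
bed for everything else. `default_breast_cohort()` draws patients from
nine course archetypes: diagnosis-only cases in each of the three age
bands, surgery-only (breast-conserving or mastectomy), BCS with adjuvant
radiotherapy, BCS followed by hormone therapy (a 10% minority with
additional radiotherapy), a multimodal course with neoadjuvant
chemotherapy, mastectomy, radiotherapy and adjuvant hormone therapy, and a
small (2%) deliberately implausible archetype whose radiotherapy is dated
before its BCS, so that data-quality workflows have something to find.

The archetype mixture weights and age-band assignments were solved once so
the generated *marginals* land on the published registry cohort's
frequencies: age bands 47.7 / 15.5 / 36.9 percent, any-surgery 63.9%,
BCS 43.9%, mastectomy 18.1%, systemic therapy 34.5%, radiotherapy 31.2%.
Within archetypes, attribute distributions are deliberately concentrated
on archetype-typical values (e.g. the multimodal chemotherapy archetype
centers on stage III and G3, the BCS+RT archetype on stage I and G1/G2)
with 10--35% missing mass per attribute and an archetype-independent 90%
missing rate for ECOG. That concentration is a design choice: the
generator's contract is that planted archetypes are recoverable (mean
within-archetype distance at least 0.2 below mean between-archetype
distance), which is the precondition for the clustering-recovery test. A
first draft that reproduced broad registry-wide attribute marginals inside
every archetype violated that contract - real attribute heterogeneity and
recoverable planted structure pull in opposite directions, and the
generator resolves the tension in favor of its role as a test bed. The
joint distribution of treatments by stage is plausibility-driven, not
epidemiological.

Perturbations make the archetypes noisy without destroying them: each
attribute is resampled with probability 0.05, non-diagnosis events are
dropped with probability 0.02, and with probability 0.01 an event is
duplicated at a later date. Diagnosis dates are uniform over 2019;
inter-event gaps are lognormal with coarse defaults (e.g. median 30 days
from diagnosis to surgery, 120 days from neoadjuvant chemotherapy start to
surgery), so neoadjuvant therapy is dated before the surgery and adjuvant
therapy after.

Survival is proportional hazards on an exponential baseline
($2\times10^{-5}$ per day, about 97% four-year survival at the reference
covariates) with planted per-archetype log hazard ratios (best: BCS+RT at
$-0.3$; worst: diagnosis-only at $1.3$, echoing the observation that
treatment-less records carry poor prognosis), plus covariate effects for
age (0.05 per year), grading, main stage and lobular histology. The truth
table records each patient's archetype, planted log-HR, full linear
predictor and uncensored event time, so tests can verify both the
clustering and the survival machinery against ground truth.
`simulate_survival_cohort()` is a stripped-down companion for calibration
studies; its uniform censoring bound is solved numerically so the expected
censoring fraction matches the request (20% by default).

## What passing tests do and do not show

The tests demonstrate, on generated data: exact agreement of the distance
arithmetic with hand-computed worked examples; equality of the
dynamic-program course distance with an exhaustive edit-script enumeration
and, under 0/1 costs, with a textbook Levenshtein implementation;
symmetry, boundedness and convexity over random events; recovery of
planted archetypes by the full embed-and-select pipeline (ARI $\ge 0.9$);
agreement of the silhouette with a naive recomputation to $10^{-9}$;
nominal coverage of Cox confidence intervals over 200 simulated cohorts;
agreement of the Kaplan-Meier estimator with a hand product-limit on all
small datasets; and the G-computation identities (identical curves under
a null cluster effect, stratified-KM equivalence for a saturated
stratified model).

They do not show that real registry courses cluster this cleanly. Real
extracts have heavier attribute heterogeneity inside clinically meaningful
groups, inter-registry coding differences, informative missingness, and
treatment mixes the generator only sketches. On real data the same
pipeline runs unchanged, but cluster counts, silhouettes and hazard ratios
should be read as exploratory summaries, not as the calibrated quantities
the synthetic tests certify. The survival comparison in particular is
hypothesis-generating: clusters are formed from treatment data alone, and
residual intercluster differences may reflect care processes, reporting
completeness or patient selection rather than treatment effects.

## Numerical choices and degenerate inputs

* Therapy-type matrix: shipped as CSV; decimal commas in user-supplied
  matrices are normalized at load time; symmetry, range, zero diagonal
  (except MI--MI $=1$) and the all-ones MI row are validated.
* Jaccard on two *documented-empty* sets is 0 (explicit "no
  complications" is informative agreement); an undocumented set is
  missing, distance 1.
* Both-empty courses: distance 0 (limit of identical sequences).
* Complication sets are encoded as 31-bit masks for the compiled kernel;
  a cohort with more than 31 distinct complication codes is rejected with
  a clear message.
* UICC substages are mapped to their main stage for distance purposes;
  the substage label enters the Cox model as a categorical level.
* Embeddings of degenerate matrices (all-zero distances, $n = 2$) fall
  back to zero-padded coordinates instead of failing.
* The survival workflow uses days throughout; 4 years $= 1460$ days.
* Cluster labels are 0-based with $-1$ reserved for outliers, matching
  the convention of the density-based algorithms.

## Problem sizes used by the test suite

The default suite generates cohorts of 40--10,000 patients and runs the
full clustering pipeline at $n = 1000$ (about 500,000 course pairs), the
Cox coverage study over 200 cohorts of 600 patients, and the exhaustive
Kaplan-Meier suite over all 126 event patterns of up to six patients.
These sizes keep a complete run in the low minutes on one core while still
exercising every code path at a scale where the statistical assertions
(coverage, recovery, marginals) are meaningful.

## Known limitations

* The course distance is not a metric in the strict sense: self-distances
  of incomplete courses are positive by design, and the triangle
  inequality is not guaranteed after length normalization.
* Only the four event types above are compared; metastasis and progression
  events are out of scope.
* Attribute weights are fixed expert choices, configurable but not
  learned.
* The embedding is 2D by construction; structure that needs more
  dimensions is flattened, and silhouette selection inherits that limit.
* HDBSCAN-style extraction implements the excess-of-mass rule without the
  library refinements (no single-cluster allowance, no cluster-selection
  epsilon).
* Registry consolidation ("best-of" merging of conflicting reports) is
  upstream of this package and out of scope.
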