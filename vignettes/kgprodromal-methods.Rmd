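---
title: "Knowledge-graph patient embeddings for prodromal disease prediction: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-graph patient embeddings for prodromal disease prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgprodromal)
```

# The problem

Neurodegenerative diseases such as Parkinson's disease (PD) have a prodromal
phase: years before the first diagnostic code appears in a patient's chart,
nonspecific autonomic, sleep and mood complaints accumulate. Individually
these codes are weak predictors; collectively, and interpreted against what
is known about disease biology, they carry signal. `kgprodromal` implements a
pipeline that makes this interpretation explicit: coded EHR concepts are
mapped onto a typed heterogeneous biomedical knowledge graph (diseases,
symptoms, genes, compounds, side effects), each concept is *propagated*
through the graph, and a patient becomes a probability vector over all graph
nodes — including biological nodes that never appear in any chart. Weighted
classifiers trained on these vectors are then compared against two baselines
(raw binary code vectors and a likelihood-ratio prodromal-criteria
calculator) at one, three and five years before the index date.

The real data behind this design — a hospital-scale OMOP EHR and a
production biomedical knowledge graph — are not distributable, so the
package ships a first-class synthetic-data module that generates both, with
a controllable planted signal, and every claim the package makes is tested
against that module. What passing tests do and do not establish is discussed
at the end.

# Propagation model

## Transition structure

A knowledge graph with \(N\) nodes yields a column-stochastic operator
\(T\): column \(j\) spreads mass uniformly over the neighbors of node \(j\).
Edges are traversed in both directions by default (the relations in
biomedical graphs — *presents*, *associates*, *treats* — are informative
both ways, and no direction-specific weighting is defined here); a directed
mode is retained behind the `orientation` flag of `buildTransition()`.
Edges are unweighted and parallel edges count once. Nodes with no
out-neighbors under the chosen orientation are *dangling*; their mass is
handed to the restart distribution at every step, the standard PageRank
convention. Nodes are ordered lexicographically by id so that every derived
matrix is reproducible across runs.

## Per-concept embeddings (PSEVs)

For a mapped EHR concept \(c\), the restart distribution \(r_c\) places mass
on each entry node in proportion to the number of cohort patients who carry
\(c\) *and* have at least one event mapping to that node (the concept's own
node always co-occurs with itself; a concept with no carriers falls back to
unit mass on its own node). The embedding is the stationary point of the
personalized PageRank iteration

\[ v \leftarrow d\,(T v + m_{\text{dang}}\, r_c) + (1-d)\, r_c , \]

iterated until the L1 change falls below `tol`. Defaults: damping
\(d = 0.85\) (the standard choice for topic-sensitive PageRank; the walk
explores roughly \(1/(1-d) \approx 7\) steps), `tol` \(10^{-8}\), 1000
iteration cap with a hard error on non-convergence. Every row of the
resulting concept-by-node matrix is a probability vector, a property the
validity method of `PSEVMatrix` enforces at \(10^{-9}\).

The cohort weighting makes PSEVs cohort- and window-specific: the package
recomputes the matrix per pre-diagnostic horizon, so the restart reflects
exactly the events visible in that analysis.

## Patient signatures (SPOKEsig)

A patient's signature is the sum of the PSEV rows of their *distinct* mapped
concepts, L1-normalized. Multiplicity is deliberately ignored — a chronic
complaint coded weekly should not dominate a signature — but a
count-weighted mode exists behind `countWeighted = TRUE` for sensitivity
analyses. Unmapped concepts are skipped and surfaced in a coverage
attribute; a patient with no mapped concept raises an explicit
"empty signature" error so the caller decides the drop policy (the pipeline
drops and logs).

# Cohort construction

All date arithmetic uses fixed-day conventions: year = 365 days, six months
= 182 days. Calendar phrases in clinical rules are inherently ambiguous;
fixed-day arithmetic makes every boundary decidable and testable.

* **Case index date** \(t_0\): day of the first disease diagnosis code, or
  the day a disease-specific medication was started if that is earlier. A
  case needs at least two diagnosis codes with a confirming code at least
  182 days after \(t_0\); otherwise the record is rejected (a value with a
  reason code, not an error).
* **Controls**: \(t_0\) = last visit minus 182 days.
* **Exclusions**: cases with a neuroleptic medication inside the half-open
  window `(firstCode - 182, firstCode]` (drug-induced parkinsonism guard),
  and any patient younger than 40 years at index. The neuroleptic window is
  anchored at the first *diagnosis code* rather than at \(t_0\): the rule
  exists to catch parkinsonism induced shortly before the diagnosis was
  coded, and anchoring at a medication-derived \(t_0\) would silently widen
  it. Each excluded patient carries exactly one primary reason
  (neuroleptic window checked before age), so exclusion counts partition
  the excluded set and the pipeline's accounting always sums to the input
  count.
* **Windows**: horizon \(h\) keeps events strictly before
  \(t_0 - 365h\). The boundary is strict and the exclusion window half-open;
  with integer day offsets every event is unambiguously in or out, and the
  windows nest (\(-5 \subseteq -3 \subseteq -1\)), which is asserted as a
  property test.
* **Prevalence sampling**: all cases are kept and controls are drawn
  without replacement down to `floor(nCases * 100000 / 572)` under the
  age-adjusted prevalence default, deterministically under a seed. The
  ratio is configurable; the packaged experiments use a 1:1 override
  because a faithful 572:100,000 design at a few hundred cases would need
  tens of thousands of controls, far beyond the intended desk scale. When
  exclusions occasionally leave fewer controls than cases under the 1:1
  override, the experiment runner trims cases (seeded, logged in the
  report's accounting) rather than aborting; `samplePrevalence()` itself
  keeps the strict contract and errors.

# Classification and evaluation

Features are the signature columns (one per graph node). The primary model
is a probability random forest with per-sample weights derived from
balanced inverse-frequency class weights \(w(\text{class}) = n/(2
n_{\text{class}})\); a ridge-penalized logistic model (fixed small
\(\lambda\), because signature columns are collinear — every row sums to 1)
is fitted alongside for the algorithm comparison. Both expose the same
scorer contract: a matrix in, case probabilities in \([0,1]\) out,
reproducible under a fixed seed.

Evaluation follows the bootstrap design: an 80:20 stratified split; on the
test set, 100 bootstrap replicates of 50 patients drawn with replacement
(replicates without both classes are redrawn); the rank-based AUC (ties
half-credit, identical to the normalized Mann–Whitney U) per replicate; and
the 95% CI as the 2.5th/97.5th percentiles of the replicate distribution.
Distributions of two methods are compared with a two-sided Welch t-test and
a two-sample Kolmogorov–Smirnov test on the replicate values.

Per-feature screening uses the two-sided Mann–Whitney U test on every
signature column (exact enumeration for small tie-free samples, normal
approximation with tie correction otherwise), with features ranked by
p-value within node type and Benjamini–Hochberg FDR reported alongside raw
p. Constant columns get p = 1 by convention and are flagged. Forest
importances (impurity; absolute standardized coefficients for the logistic
model) are converted to percentiles with the midrank convention
\(100(\mathrm{rank}-0.5)/N\) — all-equal importances score exactly 50, a
unique maximum scores \(100(N-0.5)/N\) — and the top 15 features per node
type are reported.

# The prodromal-criteria baseline

The comparison calculator combines an age-band prior with a product of
marker likelihood ratios in odds form:
\(\mathrm{odds}_{\text{post}} = \frac{p}{1-p}\prod_i LR_i\), where a marker
contributes `lr_present` when asserted by at least one coded event,
`lr_absent` when it is EHR-assessable but unobserved, and 1 when it cannot
be assessed from codes at all (exam- or imaging-based markers) — matching
the information actually available to an EHR-only comparison. The update is
associative and strictly monotone in both prior and LR, which the tests
assert as invariants.

The shipped marker table (`inst/extdata/mds_markers.tsv`) is seeded with
likelihood-ratio values from the published prodromal research criteria
literature and the age-prior table with its age-band priors, extended
downward with a small sub-50 prior so every adult is scorable. Both are
editable configuration, not a reproduction of any specific study's marker
panel; the concept-id column is deliberately synthetic. Patients with no
present marker still receive their prior as a score (ranking is all the
ROC analysis needs); `requireMarkers = TRUE` restricts to marker-positive
patients.

# The synthetic-data module

The generator is a first-class, tested component, and its defaults define
the study conditions for every packaged experiment. Design rationale:

* **Graph**: five node types (10 diseases, 60 symptoms, 30 genes, 40
  compounds, 15 side effects); a deterministic ring backbone over all nodes
  guarantees connectivity and reproducibility; 80 entry nodes (symptoms and
  compounds) are the EHR-mappable concepts. Every entry node carries one
  "presents"-style edge to a non-target disease assigned round-robin, so
  entry nodes are structurally comparable; the planted signal is a direct
  edge from each of 8 evenly spaced prodromal entry nodes to the target
  disease. Background edges appear independently with probability 0.01.
  One non-target disease is designated the *negative control*: it receives
  its backbone and round-robin wiring but no random edges and no wiring to
  the target or the prodromal entries, giving screening a feature whose
  null behavior is structurally protected. At this graph size a feature
  chosen at random would sit only a couple of hops from the planted signal,
  so "unrelated" must be built in rather than hoped for.
* **Events**: per-patient counts are Poisson (the simplest count process; no
  overdispersion or visit clustering), with days uniform over the
  observation span and concepts uniform over the entry set at `baseRate`
  total events per patient-year. The default `baseRate = 1.5` over 80
  concepts keeps per-patient concept sets sparse (roughly 5–10 distinct
  concepts in a window, i.e. ~10% of the vocabulary), which mirrors the
  sparsity of real EHR-to-graph mappings; at much higher densities the
  cohort-weighted restart distributions of all concepts converge and
  concept embeddings lose their identity.
* **Cases** get a planted index day uniform in the central 60% of a 12-year
  span (so every horizon has support for a reasonable fraction of cases),
  two diagnosis codes at least 182 days apart, a preceding disease-specific
  medication for 20% of cases (exercising the medication-first index rule),
  and a neuroleptic tag for 5% (exercising the exclusion). Ages are drawn
  at the *index date*, uniformly over 35–85 years, identically for both
  arms — age must not be a confound unless a test plants one — and the
  under-40 tail exercises the age rule. Controls draw their index day from
  the same distribution as cases so the two arms have the same pre-index
  exposure time; an early version of the generator pinned control index
  dates near the end of the span, and the resulting exposure imbalance
  dominated every comparison, an instructive failure mode for EHR
  case-control designs in general.
* **Signal**: prodromal-concept rates among cases are multiplied by a
  band-dependent factor: ×6 within the final pre-index year, ×4 between one
  and three years, ×3 beyond three years (non-increasing with distance is
  enforced — prodromal symptoms grow more numerous as diagnosis nears).
  Because every analysis window already discards the final pre-index year,
  the nearest band is invisible to all horizons — mirroring the design
  decision to ignore the year before the first code, where diagnostic delay
  blurs labels. The -1 window therefore sees the ×4 and ×3 bands, the -3
  and -5 windows only the ×3 band with shrinking exposure, which is what
  produces the expected AUC ordering across horizons. Magnitudes were
  chosen once so that discrimination at the closest horizon is moderate
  (bootstrap AUC around 0.75–0.85) rather than saturated, the regime the
  method is meant for.
* **Relayed cohorts** (`generateRelayedCohort()`) construct the scenario
  where enrichment is *necessary*: training-fold cases express one half of
  the prodromal concepts, test-fold cases the disjoint other half, and
  prodromal concepts never occur as background noise. A raw binary model
  trained on the A-half sees literally nothing of the B-half at test time;
  the propagated signatures of both halves load on the same target-disease
  feature. The fold assignment replaces the random split.

Identical spec (seed included) gives byte-identical output; every generator
is a pure function of its spec.

## What the synthetic data does not emulate

No real vocabularies or concept hierarchies; no coding-habit or
utilization artifacts (the frequency of *visits* carries signal in real
EHRs); no lab values or abnormal flags (labs enter as concept presence
only); no age- or sex-dependent background rates; no edge weights or
evidence scores on the graph. Passing tests therefore demonstrate that the
implementation is faithful to the stated model and that the method recovers
a planted, graph-mediated signal under controlled conditions — not that it
would achieve any particular accuracy on hospital data.

# Numerical and engineering choices

* Node order is lexicographic in the C locale everywhere; ties in relay
  ranking and top-k lists break by node id; all matrices carry dimnames.
* The propagation loop renormalizes its result once at convergence to absorb
  accumulated rounding at the \(10^{-15}\) level; conservation is asserted
  at \(10^{-9}\).
* Matrix Market export writes 17 significant digits so reload is bit-exact.
* A single experiment seed fans out to per-stage seeds through a documented
  rolling hash of the stage name (`stageSeed()`), keeping every stage
  independently re-runnable and all seeds below \(2^{31}\).
* Packaged experiments and tests run at deliberately small problem sizes —
  graphs of ~155 nodes, cohorts of 200 cases and 200 controls, forests of
  300 trees, 100 bootstrap replicates — chosen so the full replica
  experiment completes in seconds while keeping every qualitative contrast
  (signal recovery, horizon ordering, enrichment advantage) comfortably
  away from its decision boundary.

# Known limitations

The restart-weighting variant of topic-sensitive PageRank implemented here
is one reasonable reading of cohort-weighted propagation; alternatives
(e.g. prevalence-scaled entry weights) are isolated behind
`buildRestartVector()` and can be swapped without touching the propagation.
The signature screen inherits a small systematic coupling from L1
normalization: when one region of the graph gains mass in one arm, every
other feature loses a little, so at large cohort sizes even structurally
unrelated features drift from the null. The designated negative-control
disease bounds this effect in testing; users screening real data should
interpret weakly significant depletion signals with that coupling in mind.
Pre-diagnostic windowing drops patients whose history is shorter than the
horizon, so distant-horizon analyses run on smaller, survivor-biased
cohorts — as in the underlying study design.
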