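---
title: "Methods: temporal disease associations and trajectory DAGs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal disease associations and trajectory DAGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajmine)
```

## The problem and the data model

Administrative inpatient registries record one row per hospitalization:
a within-edition patient identifier, an admission date, an ordered list of
billed ICD-9-CM diagnosis codes (the first being the principal diagnosis),
an in-hospital death flag, and the patient's age. Two structural quirks of
such registries shape the whole pipeline:

* **Editions cannot be linked.** Annual releases ("editions") re-identify
  patients, so the same person carries different identifiers in different
  editions. Naively pooling editions double-counts patients. The merge rule
  implemented in `merge_editions()` keeps the latest edition wholesale and,
  from earlier editions, only patients with an in-hospital death there — a
  deceased patient cannot reappear later, so the union is redundancy-free.
* **Only intervals are meaningful.** The data are deidentified;
  `admission_day` is an integer offset from an arbitrary epoch. All windows
  below are in days.

Preprocessing reduces admissions to per-patient *timelines*: the principal
diagnosis of each admission is truncated to the three-digit ICD-9-CM level
(so sub-classifications of one condition are analysed together), admissions
whose principal code is not a disease are dropped (pregnancy 630–679,
injury/poisoning 800–999, E codes, V codes), and only the *first* admission
per disease is kept. Death is terminal: records dated after a patient's
earliest death-flagged admission are dropped with a warning.

Two chapter-range decisions were genuinely open. The four excluded
categories are named but not enumerated in the registry literature we
follow; we pin them to the ranges above and note that perinatal-condition
codes (760–779) are *retained*, as they are not one of the four named
categories. Both choices are localized in `filter_nondisease()`.

## Pair association

For a cohort of $N$ patients with per-disease incidences $I_i$ (patients
ever first-diagnosed with $i$), and $C_{ij}$ the number of patients whose
first diagnoses of $i$ and $j$ lie within the window of each other, the
relative association is

$$\mathrm{RA}_{ij} = \frac{C_{ij}}{C^*_{ij}}, \qquad
  C^*_{ij} = \frac{I_i\,I_j}{N}.$$

Significance is the one-sided upper binomial tail
$P(X \ge C_{ij})$, $X \sim \mathrm{Bin}(N, I_iI_j/N^2)$, and
Benjamini–Hochberg adjustment is applied once over all pairs with both
incidences positive. Pairs with $\mathrm{RA} > 1$ and $q < 0.1$ are kept.

Numerical and interface choices:

* **$N$ is the merged-cohort size**, not the number of patients with a
  disease-coded admission: an inpatient registry contains every admitted
  patient, including those whose admissions are all filtered as
  non-disease. `pair_associations()` therefore takes `n_total`;
  `run_pipeline()` passes the merged-registry patient count. With the
  default (timeline patients only) RA would be biased downward by the
  fraction of disease-free patients.
* **The window is inclusive** (gap ≤ `window_days`, default 365). "Within
  one year" admits either reading; the inclusive one is adopted for both
  the association and the direction stage, and the boundary is tested.
* **The test is one-sided** because only excess co-occurrence is ever
  selected (the RA > 1 filter); the lower tail is never of interest.
* **The null expectation ignores the window** while the observed count
  applies it. With long observation spans this makes the test strictly
  conservative for pairs whose co-diagnoses are spread out in time; the
  calibration experiment below therefore uses the full window, which makes
  the binomial null exact.
* Pairs with a zero incidence are never tested and carry no
  multiple-testing penalty; $C_{ij} = 0$ gives RA $= 0$, $p = 1$.

## Temporal direction

For each patient $p$ diagnosed with both diseases within the window,
$d^p_{i\to j} \in \{-1, +1\}$ indicates whether $i$ came strictly first;
$\delta_{i\to j}$ is the mean of the $d$'s. Same-day pairs are excluded —
$d$ is defined only on $\{-1, +1\}$, and dropping ties is the standard
sign-test treatment. $\delta_{i\to j} = -\delta_{j\to i}$ by construction.

Significance is the exact two-sided sign test (doubled smaller tail of
$\mathrm{Bin}(n, 1/2)$, capped at 1): two-sided because the selection
criterion is $\delta \ne 0$, with the orientation decided afterwards by the
sign. The BH family at this stage is separate from the association family —
each criterion controls its own FDR over the pairs it tests. Inter-diagnosis
interval summaries (mean, SD with $n-1$) are computed over forward-ordered
patients only, since they describe the oriented transition.

## Greedy trajectory DAGs

Significant directed pairs, sorted by descending patient count (ties broken
lexically on source then target, so runs are deterministic), are
concatenated: from every disease that appears as a source, paths grow by
attaching pairs whose source equals the path's terminal and whose target is
not already on the path; an extension is kept only if at least one patient
*follows* the whole extended sequence — first-diagnosis days strictly
increasing with every consecutive gap within the window (the same 365 days
as the pairwise stage). All viable extensions are attached, so nodes branch;
each root-to-terminal path keeps its own follower count, which is monotone
non-increasing under extension. Growth stops when no extension has a
follower. Where followers of a final path died in hospital on or after its
last diagnosis, a distinguished death terminal (out-degree 0) is appended.

Three decisions the terse greedy description leaves open:

* **Acyclicity is enforced during growth.** Pairwise orientation is not
  transitive: three pairs can orient as $A\to B$, $B\to C$, $C\to A$, each
  individually significant. Paths are always acyclic (no repeated node),
  but their union need not be, so an extension whose edge would close a
  cycle in the accumulated graph is skipped. Two-cycles in the *input* are
  impossible for pairs produced by `directed_pairs()` (antisymmetry) and
  raise an error if forced.
* **Death is an optional terminal**, not a required one: trajectories whose
  followers all survive are retained without a death node.
* **Patients are counted per path.** When paths share a prefix their
  follower sets overlap; node and edge annotations use the union of
  distinct patients over all prefixes through that node or edge, so an
  edge's count never exceeds either endpoint's. Path rows report the
  full-sequence count. No cap is placed on path length; it is data-limited.

`export_dag()` serializes a DAG to JSON (lossless, see `dag_from_json()`),
Graphviz DOT (death drawn as a box) or GraphML with node/edge attributes.

## Cohort validation statistics

`relative_risk()` uses the standard log-RR Wald construction:
$\widehat{\mathrm{RR}} = \frac{a/(a+b)}{c/(c+d)}$ with
$\mathrm{SE}(\log \mathrm{RR}) = \sqrt{1/a - 1/(a+b) + 1/c - 1/(c+d)}$,
a normal CI on the log scale and a two-sided normal p-value. Zero outcome
cells abort unless the Haldane–Anscombe correction (+0.5 to every cell) is
requested. `hypergeom_enrichment()` is the upper tail $P(X \ge k)$;
`rate_report()` expresses count ratios as rounded percentages with optional
fold against a reference incidence. These operate on explicit counts so
published cohort arithmetic can be reproduced exactly from printed numbers.

## The synthetic registry generator

`sim_config()` + `generate_registry()` emulate the structure of a
multi-edition inpatient registry: per-patient disease memberships, admission
days over a configurable study window (default 7300 days ≈ 20 years of
longitudinal coverage), sub-classified principal codes ("728.88") and
secondary diagnoses to exercise rounding and principal selection, a
configurable fraction of non-disease admissions to exercise chapter
filtering, death attached to a patient's last admission with a per-code
hazard (default 0.2, giving roughly the ~20% patient-level death fraction
typical of such registries), and annual editions in which earlier editions
contain only deceased patients. Every cohort member receives at least one
admission, matching the registry semantics of $N$ above.

**Planted effects.** Each disease is a Bernoulli draw at its baseline rate
(default 0.05). For a planted pair $(i, j, \text{lift})$ the target's
membership is redrawn conditionally:
$P(j \mid i) = \min(1, \text{lift}\cdot p_j)$ and
$P(j \mid \neg i) = \max\!\big(0, (p_j - p_i P(j\mid i))/(1-p_i)\big)$,
so the joint probability is $\text{lift}\cdot p_i p_j$ *and the target's
marginal stays exactly $p_j$*. The simpler coupling that only boosts
$P(j\mid i)$ inflates the target's marginal by $1 + p_i(\text{lift}-1)$ and
biases the recovered RA below the planted lift by up to ~10% at realistic
rates; the marginal-preserving form makes $E[\mathrm{RA}] = \text{lift}$
without a rare-disease approximation. When $\text{lift}\cdot p_j > 1$ the
conditional probability is capped with a warning naming the pair.

**Intervals and direction.** Co-diagnosed planted patients get an
inter-diagnosis gap drawn from a normal distribution truncated (by
rejection) at ≥ 1 day, ordered source-first with probability
`direction_prob`; pairs pushed outside the study window are shifted back
jointly, preserving the gap. The default interval parameters
(mean 114.9, SD 84.3 days) are on the scale of within-year readmission
intervals. Note that truncation shifts the realized mean upward: with the
defaults the expected *observed* mean gap is ≈ 130 days, and that is what
estimators recover — the configured values parameterize the untruncated
parent, not the observed moments. Unrelated diseases get independent
uniform days over the study window, so their pairwise gaps are mostly far
beyond one year.

**What the generator does not emulate:** hospital-level clustering,
seasonal admission patterns, coding-practice drift, age- or sex-dependent
incidence, and any dependence structure beyond pairwise coupling. Passing
tests on simulated registries therefore validate the *statistical
machinery* — calibration of the tests, recovery of planted effects,
correctness of the greedy search — not the clinical plausibility of
trajectories mined from any particular real registry.

## Validation experiments and problem sizes

The test suite fixes these study conditions:

* **Calibration under independence.** On a null registry (all lifts 1,
  8 diseases at rate 0.15, 5,000 patients) the empirical RA of every pair
  lies within 3 Monte-Carlo SE of 1, computed with the full window so the
  membership coupling is isolated from day placement.
* **False-discovery control.** Over 20 null registries (30 diseases, rate
  0.05, 20,000 patients each) the realized false-discovery proportion of
  the RA stage at FDR 0.1 — under a global null, the fraction of registries
  with any discovery — stays within 0.1 plus 3 Monte-Carlo SE.
* **Parameter recovery.** A registry of 50,000 patients with one planted
  pair (lift 3, direction 0.9) yields RA within 15% of 3 and δ within 0.1
  of $2\times0.9 - 1 = 0.8$, with the pair correctly oriented end-to-end.
* **Greedy versus exhaustive.** On 50 random small registries (5 diseases,
  120 patients) every greedy path is reproduced by exhaustive enumeration
  with identical follower and death counts, via an independent per-patient
  counting oracle; all DAGs verify acyclic.
* **Exact-tail oracles.** The binomial, sign-test and hypergeometric tails
  and the BH adjustment match brute-force enumeration on all instances up
  to n ≈ 25–30 at 10⁻¹².

`scripts/acceptance.R` re-runs the recovery and null-FDR experiments from a
caller-supplied seed and reproduces published cohort arithmetic from printed
counts, writing everything as JSON.

## Known limitations

* First-occurrence collapse discards readmission multiplicity; trajectories
  cannot revisit a disease by design.
* The binomial null treats incidences as fixed; at very high disease
  prevalences the variance of $C_{ij}$ is overstated and the test becomes
  more conservative.
* The windowed count against an unwindowed expectation means RA is not
  calibrated to 1 under independence when diagnoses are spread far beyond
  the window — it is a selection statistic, not an effect estimate, and
  planted-lift recovery holds when the planted intervals lie within the
  window.
* Greedy growth with the cycle-skip rule is order-dependent by intention
  (the sort order is part of the algorithm's definition); a different sort
  would yield different, equally supported DAGs.
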