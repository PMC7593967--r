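---
title: "Classifying and partitioning whole-community microbial invasions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and partitioning whole-community microbial invasions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invasim)
```

## The experimental design this package analyses

`invasim` targets factorial community-coalescence experiments: four source
communities (MC1–MC4) pre-adapted to two resource environments (plant
litter, R2A agar), of which two (MC1, MC2) serve as established *residents*
and all four as *invader inocula*. Invasions cross invader × resident
(invader ≠ resident) × dose (high = 1×, low = 0.25×) × introduction
frequency (1× or 4×), with three replicate microcosms per cell: 144 invaded
finals. Controls comprise resident-resident mixes (perturbation control,
48) and killed-inoculum additions (necromass control, 48), for 240
microcosms in total, plus inoculum and initial-resident sequencing samples.
An *invasion event* is one (environment, resident, invader) combination —
six per environment, twelve in all.

## OTU invasion-category classification

For one event, three pooled presence groups are formed: the invader
inoculum samples (I), the composite resident control (R: initial resident,
resident-resident finals, killed-inoculum finals of that resident), and the
final invaded communities across all doses and frequencies (F). An OTU is
*present* in a group if it has at least one read in at least one sample of
the group. The seven presence patterns map onto six categories (invader,
noninvasive, resilient, nonresilient, common, undetermined), which
partition the event's OTU universe `|I ∪ R ∪ F|`, the denominator for
category percentages.

Three choices deserve explanation:

* **Any-sample presence.** The control group is a composite precisely to
  strengthen detection of resident taxa (fewer false "invader" calls); an
  all-samples rule would defeat that purpose.
* **Union universe.** With `|I ∪ R ∪ F|` as denominator the six categories
  are exhaustive and percentages sum to 100 by construction.
* **Pooling doses and frequencies within an event.** Establishment under
  *any* delivery regime counts as invasion; dose/frequency effects are
  assessed separately by the variance-partitioning module.

Because presence is evaluated on rarefied counts, category membership near
the detection limit can flicker between rarefaction draws. The analysis
therefore repeats rarefy → classify → summarise (100 repetitions by
default), averages category percentages *as percentages*, and records for
every OTU its modal category together with the fraction of rarefactions
supporting it — downstream scoring fixes each OTU-event instance at its
modal category and carries the supporting fraction as a diagnostic.
Depth-robustness is checked with a G-test of independence
(`G = 2 Σ O ln(O/E)`, chi-square reference) on the rounded mean category
counts per depth; counts, not percentages, enter the test because G-tests
require frequencies.

"Undetermined" OTUs (final community only) are interpreted as
detection-limit artifacts: the inoculum group typically has the fewest
pooled samples and hence the weakest detection. Consistently, the expected
undetermined fraction grows as the rarefaction depth shrinks — the test
suite checks this trend on synthetic data over depths 500 → 1,020 → 5,000.

## Family-level competitor scores

Within a family, each (OTU, event) with modal category invader or resilient
is one *strong* instance — both outcomes are successful competition, and
the same OTU may be resilient in one event and invasive in another. With
`k` instances and `N` the mean relative abundance (percent scale) of the
OTU in its initial pool (inoculum for invader-side instances, resident
control for resident-side) and in the final communities:

* strong score: `(Σᵢ N_final,i / N_initial,i) × k`
* weak score (noninvasive + nonresilient instances): `(Σᵢ N_initial,i) × k`

OTUs with family confidence below 70% are excluded. Bacterial families are
reported when the raw score exceeds 50 in *both* environments; fungal
families on the litter score alone (fungal communities collapse on agar).
Retained scores are averaged across qualifying environments and reported as
square roots (a display transform; the threshold applies to the raw score).
Families must qualify at every configured rarefaction depth. The percent
scale for `N` matters only for the weak score (the strong score is a ratio
and scale-free): on a 0–1 scale the weak sum is bounded near `k²·mean
abundance` and the conventional >50 threshold would be unreachable, so the
package treats abundances as percentages throughout scoring.

## Variance partitioning

Univariate responses (CO₂, DOC, richness, Shannon) are decomposed by
sequential (Type I) fixed-effects ANOVA with terms entered as dose,
frequency, invader, resident, then interactions; on the balanced parts of
the design Type I/II/III coincide for main effects, which is why no Type
III machinery is provided. Composition is decomposed by PERMANOVA in the
McArdle–Anderson formulation: the Gower-centred inner-product matrix of the
squared Bray–Curtis distances is projected onto the sequential term spaces
(a Gram–Schmidt construction robust to the rank deficiency that incomplete
invader × resident cells induce), pseudo-F is `(SS_term/df_term) /
(SS_res/df_res)`, and p-values come from free permutation of sample labels
with the +1 convention, so the smallest attainable p is `1/(n_perm + 1)`.
The PERMANOVA/ANOVA identity on Euclidean distances of a univariate
response is the module's central correctness oracle, checked to 1e-8
against the classical F and against `vegan::adonis2`.

Full models are reduced to terms with `p < α` (default 0.05), closed under
the hierarchy rule (a retained interaction forces its main effects — the
source only says "significant factors", so the hierarchy closure is this
package's choice). Percent variance is then estimated on the reduced
models. The literature the design follows cites external estimators without
formulas, so the package commits to two documented ones behind a stable
contract: omega-squared-style components for ANOVA,

> `ω²ₜ = (SSₜ − dfₜ·MS_res) / (SS_total + MS_res)`,

negatives truncated to zero and the set rescaled to sum to 100 with the
analogously-formed residual; and plain sequential-SS shares
(`100·SSₜ/SS_total`) for PERMANOVA. Analyses run separately per environment;
invaded-vs-control contrasts use one-way ANOVA (univariate) and pairwise
PERMANOVA with Benjamini–Hochberg adjustment (the source does not state a
correction; BH is the field default).

## What the synthetic generator emulates — and what it does not

`generate_dataset()` reproduces the *statistical* structure the analysis
assumes, not community dynamics:

* **Pools.** Each source community holds `n_otus_per_pool` OTUs (default
  250) of which a fraction `pool_overlap` (default 0.4) is shared by all
  four — so the pairwise shared-taxon fraction equals the parameter by
  construction, and the union universe of an event (~400 detectable OTUs)
  matches the scale of real 97%-OTU bacterial tables. Relative abundances
  are log-normal (`sdlog` 1.5), putting a realistic heavy tail of
  near-detection-limit taxa into every pool.
* **Invasion outcomes.** Inoculum-only OTUs establish with probability
  `establishment_prob` (default 0.015) per introduction, doubled at high
  dose (`dose_effect` 2), with the 4× frequency treatment modelled as four
  independent establishment opportunities rather than a dose multiplier —
  mirroring the introduction schedule. Displacement of resident OTUs
  (`displacement_prob` 0.45) is drawn once per event: losses are treated as
  an outcome of the biotic interaction between the two communities, not of
  the delivery regime. Established invaders join the final community at
  `invader_boost` (3×) times their inoculum abundance — establishment means
  growth. These defaults give planted category proportions (invaders ≈ 8%,
  resilient ≈ 20%, common ≈ 13%) in the range reported for real coalescence
  experiments.
* **Sequencing.** Reads are multinomial draws at library sizes uniform
  within ±20% of `depth_mean` (default 15,000, comfortably above the
  10,000 rarefaction cutoff); killed-inoculum controls re-use the resident
  profile unchanged, since necromass contributes no distinct sequence
  signal in this emulation.
* **Functioning.** Factor-effect vectors are constructed inside the
  sequential orthogonal complements of the realised invaded design and the
  noise vector is orthogonalised against the full four-way model space, so
  the sequential ANOVA decomposition of the generated response recovers the
  scenario's `variance_shares` (default invader 60%, resident 20%, dose
  10%, residual 10%) *exactly*; omega-squared estimates then deviate only
  by their degrees-of-freedom corrections. `noise_sd` sets the residual
  standard deviation (default 1 on a grand mean of 100 CO₂ units).

Not emulated: mechanistic population dynamics, taxon–taxon interaction
structure, time courses, chimeras or any sequence-level error process, and
compositional coupling between functioning and the OTU table (functioning
variance shares are planted directly). Passing tests therefore demonstrate
that the *analysis* is correct and calibrated under the design's sampling
model — not that any particular biological conclusion transfers to real
data.

## Numerical and reproducibility choices

* Rarefaction is classic subsampling without replacement
  (`vegan::rrarefy`); samples below the target depth are dropped with a
  warning rather than an error, since that situation only arises at
  user-chosen cutoffs above the minimum library size. Shannon diversity
  uses the natural log (configurable).
* One master seed spawns named sub-streams per (stage, event, repetition)
  via a string-hash derivation, so repetition *r* of event *e* is
  reproducible in isolation and `run_pipeline()` is byte-identical across
  runs with the same configuration.
* Sample standard deviations (n−1) are used across events; percentages are
  averaged as percentages, not counts.
* Degenerate inputs are defined, not fatal: constant responses give F = 0
  with p = 1; an empty retained-term set yields a 100%-residual partition;
  fully aliased terms are reported by name.

## Problem sizes used by the test-suite

The distributional checks run at deliberately chosen sizes: classification
oracle sweeps over 1,000 random membership instances; score-formula
equivalence over 1,000 random instance lists at 1e-12; rarefaction
expectation over 10,000 draws against the hypergeometric standard error;
type-I calibration of PERMANOVA over 200 null datasets (n = 24, 999
permutations, acceptance band 0.02–0.09); variance-share recovery over 20
simulated datasets of the full 144-microcosm invaded design (±7 percentage
points); and end-to-end invader recovery on the full default scenario at
depth 5,000 with 100 rarefactions (sensitivity ≥ 0.90). Smaller structural
tests use a reduced scenario (40 OTUs per pool, mean depth 1,200) that
keeps every design count — 240 microcosms, 144 invaded, 12 events — intact.

## Known limitations

* Category flicker is resolved by the modal rule; ties at 50% support are
  broken by the fixed category order. The supporting fraction is exported
  so users can filter harder.
* The percent-variance estimators are one defensible pair among several;
  alternative estimators can be substituted behind
  `variance_components_anova()` / `..._permanova()` without touching the
  model-fitting contract.
* PERMANOVA uses free permutation (no strata), appropriate for the
  unrestricted design analysed here but not for blocked or repeated-measure
  variants.
* The generator's taxonomy (~40 synthetic families) is coarser than a real
  RDP-classified table, so family-level score distributions are denser than
  in real data; family counts in reports are dataset properties, not
  literature estimates.
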