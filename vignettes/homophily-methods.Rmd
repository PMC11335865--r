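---
title: "Measuring homophily and tie reciprocity in directed social networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring homophily and tie reciprocity in directed social networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sociomix)
```

`sociomix` quantifies how strongly same-gender online ties segregate by
age and body mass index, and whether trait similarity predicts the
reciprocation of a follow. This vignette describes the statistical
machinery, the choices behind its defaults, and what the synthetic test
bed does and does not establish.

## Data model and cleaning

The unit of observation is a directed tie: user A (the *follower*)
follows user B (the *followee*); B need not follow back. Nodes carry
self-reported gender, age, height, and mass. Because self-reports include
typos and joke values, attributes outside intuitive plausibility windows
are set missing rather than trusted: age outside 12–59 years, height
outside 140–200 cm, mass outside 10–200 kg, and BMI outside 15–35 kg/m².
All intervals are closed — a value is removed only when it strictly
exceeds a bound. BMI is always recomputed as mass/(height/100)² from the
*surviving* height and mass, never read pre-computed, so the filtering
cascade is well defined: an implausible height removes the BMI too, and a
plausible height/mass pair with an implausible ratio loses only the BMI.
Filtering is idempotent.

The analysis sample is then restricted to users with known gender, age,
and BMI whose age falls in the closed window 15–32 years — young adults,
where self-reported ages concentrate and where mating-related social
pressures are most plausibly at play. Edges touching any excluded user
are dropped entirely: every analysis needs both endpoints' attributes, so
partial dyads carry no information here. Self-loops and duplicate ordered
pairs are removed at network construction; the assortativity and dyad
machinery assume a simple directed graph.

The Pokec snapshot dialect (tab-separated, no header) is parsed
positionally; height and mass are extracted from the free-text body field
as the first number followed by "cm" / "kg" (decimal commas accepted).
The original extraction pipeline behind such snapshots is not documented
anywhere, so this parser is a documented stand-in: it is exact on the
package's own fixtures and deliberately conservative (an absent pattern
is missing data, never a guess). The raw gender flag's coding is
configurable (`gender_map`), defaulting to 1 = man.

## Assortativity

For a numeric attribute, Newman's assortativity coefficient on a directed
graph is the Pearson correlation of the attribute over the ordered edge
endpoint pairs: one (follower value, followee value) pair per stored
directed edge. Nothing is symmetrised — a reciprocal pair contributes its
two ordered pairs. The coefficient is reported as undefined (`NA`) when
the edge set is empty or either endpoint sequence has zero variance, and
in conditioned analyses also when a bin holds fewer than `min_edges`
edges (default 10). The default exists because sparse bins produce wild
coefficients; its exact value is a judgment call, exposed as an argument.

Age and BMI correlate, so apparent homophily in one trait can be an
artifact of the other. `conditioned_assortativity()` therefore restricts
the network to consecutive bins of the conditioning trait — default
widths 3 years (age, window 15–32) and 2 kg/m² (BMI, window 15–35),
half-open `[lo, hi)` with the last bin closed so the bins partition the
range — and computes the target trait's assortativity inside each bin.

## The degree-class null model

An assortativity coefficient has no sampling error attached, and "no
segregation" is not the same as *r* = 0 once activity levels and
attributes are coupled (e.g. if older users follow and are followed
more). The chance level is therefore estimated structurally: the
(gender, age, BMI) attribute *bundles* are permuted uniformly at random
among nodes with the exact same (in-degree, out-degree) pair, keeping the
adjacency bit-identical. Bundles move as intact triples, preserving the
age–BMI–gender covariance. Any statistic is then recomputed on the
shuffled network; crucially the statistic must re-derive its own subsets
(the same-gender restriction happens *after* shuffling, via
`same_gender_assortativity_stat()`), otherwise degree–attribute coupling
is destroyed and the chance level is biased toward zero.

The ensemble (default 100 replicates, as small ensembles already pin the
null mean to two decimals at these network sizes) yields a null mean and
a 95% interval; the observed value is called different from chance when
it falls outside. Two interval readings are implemented because the
choice is genuinely ambiguous: `normal_mean` (default) is a normal-theory
confidence interval for the *mean* null coefficient, mean ± 1.96·sd/√R;
`percentile` is the empirical 2.5–97.5% band of the replicate
distribution. The former asks "is the observed value consistent with the
average chance coefficient" and is very narrow; the latter is the
calibrated test of "could this single value have arisen by chance" (its
false-positive rate is the nominal 5%, which the test suite verifies on
i.i.d.-attribute networks). Readers comparing a single observed
coefficient against the band should prefer `percentile`; the default
mirrors the mean-comparison convention in the descriptive network
literature.

Two practical notes. In small networks most degree classes are
singletons, so shuffles move few attributes and the null mean sits close
to the observed value: the test is conservative there, and only
adequately powered at thousands of nodes. And because the permutation is
within-class, the null preserves *any* structure mediated by exact degree
pairs — that is the point, but it means the null is a test of homophily
beyond activity patterns, not beyond all confounding.

## Dyadic mixed models

The dyad table has one row per ordered same-gender tie with both users'
traits, the signed differences (follower minus followee), the absolute
differences, and a reciprocity flag. A reciprocal pair appears twice,
once per direction, matching the long-format convention in which a user
appears once per relationship; `dedupe_reciprocal` collapses to one row
per pair for sensitivity analyses.

**Trait similarity (Models 1–2).** On reciprocal ties only — mutual
relationships are the ones where similarity should matter most, and
reciprocity itself is modelled separately — the followee's trait is
regressed on the follower's trait, dyad gender, and the signed difference
in the *other* trait, full factorial, with a random intercept per
follower absorbing the dependence among a follower's many dyads. Outcome
and continuous predictors are z-scored over the dyad table before
fitting, so coefficients are standardized and the focal slope is the
regression counterpart of the assortativity coefficient (the two agree on
covariate-free synthetic networks, which the tests check). Fitting is by
maximum likelihood (`lme4::lmer`, bobyqa), and "all possible
interactions" is taken literally, including the three-way term.

**Tie reciprocity (Model 3).** On all ordered same-gender dyads, a
binomial-logit mixed model of the reciprocity flag on the standardized
absolute age and BMI differences, dyad gender, and all interactions
(including the three-way term — the data can make the gender difference
in the BMI effect fade at large age differences, and only the full
factorial can express that). A per-follower random intercept is included
by default: the model family is a GLMM and dyads sharing a follower are
clearly dependent; because the literature is not always explicit about
random-effect structure in this setting, a fixed-effects-only logistic
fit (`random_intercept = FALSE`) is available for side-by-side
comparison. Estimation is by Laplace approximation (`lme4::glmer`,
bobyqa). Quasi-separation is flagged (extreme estimates or standard
errors), not raised.

Fixed-effect p-values are Wald tests on the normal reference. With
dyad tables of thousands of rows the difference from a t reference or
from finite-sample corrections (Satterthwaite, Kenward–Roger) is
negligible, and the package deliberately avoids the heavier machinery.

**Per-gender slopes.** With treatment coding (reference "woman"), the
women's simple slope of a focal predictor is its main effect and the
men's adds the focal × gender interaction, both evaluated at 0 — i.e. at
the mean — of the other standardized covariates; the interaction's
p-value tests the gender difference. This is ordinary contrast algebra on
the fixed effects rather than separate per-gender fits, so the two slopes
share one error model.

**Contrasts.** Predicted reciprocity probabilities are evaluated on the
fixed-effects (population-level) scale with the random intercept at 0,
mapping raw-scale differences (default |ΔBMI| from 0 to 10 kg/m², |Δage|
fixed at 0) through the standardization recorded at fit time. The change
is reported both in percentage points, 100·(p₁ − p₀), and relative to the
starting probability — a "k% decrease in likelihood" reads either way,
so both numbers are always present. Requests outside the range of
differences observed at fit time attach a warning (extrapolation).

## The synthetic generator

`synth_config()` defines a population whose structure mirrors what the
analysis assumes about real data: gender i.i.d. Bernoulli (default 0.5);
age uniform on 15–32 (or a discretized right-skewed skew-normal clipped
to 12–59, for exercising the cleaning path); BMI a per-gender linear
function of age plus Gaussian noise, clipped to 15–35. Defaults — women's
intercept 19.6, men's 23 kg/m² at the window midpoint; slopes 0.12 vs
0.30 kg/m² per year; residual SDs 2.6 vs 2.3 — were chosen once so the
generated population shows the features the method must cope with: a
large standardized BMI gender gap (Cohen's d ≈ 1.2) and a BMI–age rank
correlation about twice as strong in men (≈ 0.5 vs ≈ 0.25).

Ties form by sampling ordered candidate pairs and accepting with
probability `plogis(θ₀ + θ_g·same_gender + θ_a·|Δage| + θ_b·|ΔBMI|)`;
negative θ_a/θ_b produce homophily. Candidate counts are calibrated from
a 20,000-pair pilot estimate of the mean acceptance probability so the
realised mean out-degree lands within a few percent of its target
(default 8) without enumerating all n² pairs; a hard cap of 500× the
target edge count bounds memory when ties are made near-impossible.
Reciprocation then adds the reverse of each one-way edge with probability
given by a full-factorial logit in the standardized absolute differences
(defaults γ_age = −0.19, γ_bmi = −0.08, with man-man modifiers +0.02 and
+0.04 and a small negative three-way term, echoing the regime the models
are built to detect: reciprocity falling with trait distance, more
steeply for women on BMI). Generating coefficients and the
standardization are attached to the edge list so recovery tests can
compare like with like — note the generator z-scores over one-way edges
while a fit z-scores over all dyad rows, so exact comparisons must
rescale by the ratio of the two SDs.

What the generator does *not* emulate: heavy-tailed degree distributions
(out-degree is approximately Poisson around the target), community or
geographic structure, missing/erroneous self-reports beyond what the
clipping produces, and any coupling between degree and attributes.
Passing recovery tests therefore show that the estimators are correct
under the stated generative model — not that real networks satisfy that
model. The degree–attribute coupling that makes the null model
interesting is absent by default and is constructed explicitly in the
tests that exercise it.

Two details of fixture emission: heights are drawn per gender and masses
back-solved from BMI, so the Pokec body-text path ("172 cm, 55.3 kg")
round-trips exactly; and because the emitted height/mass are rounded, the
re-derived BMI can sit up to ~0.03 outside the clip boundary — the
clipping applies to the latent value, and the boundary users may then be
(correctly) filtered at analysis time.

## Determinism and numerical choices

Every generator and the null ensemble accept a seed; the pipeline draws
one seed per stage from its top-level seed, so a config reproduces its
report bit for bit (timestamps excluded). Undefined statistics on
shuffled replicates are excluded with a warning (all-undefined is an
error). Zero-variance columns make standardization fail loudly with the
column name. Ties in the Spearman correlation use average ranks. Cohen's
d uses the pooled SD with the men-minus-women sign convention. The
BMI-difference sign convention is follower minus followee throughout.

Problem sizes in the test suite were chosen to keep the full run in a few
minutes while leaving Monte-Carlo error well below the tested margins:
assortativity oracles on 200 random graphs of up to 50 edges; shuffle
conservation on a 1,000-node network; null calibration at 2,000 nodes ×
200 replicates × 20 repeats; parameter recovery at 20,000 dyads × 20
seeds; the end-to-end chain at 4,000 nodes. The acceptance script uses
5,000 nodes and 100 null replicates.

## Limitations

The package analyses simple directed graphs only: no weights, no
categorical assortativity, no per-node (local) assortativity, no
edge-rewiring (configuration-model) nulls, no crossed random effects
(followee intercepts) or random slopes. The similarity/reciprocity models
treat the two rows of a reciprocal pair as exchangeable observations;
followee-side dependence is not modelled. And all conclusions about
gender differences are conditional on the platform's self-reported binary
gender field.
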