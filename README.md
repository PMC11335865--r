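# sociomix

Homophily — the tendency of social ties to connect similar individuals —
is a basic organising force in human social networks, and men and women
may express it to different degrees for different traits. `sociomix` is an
R package for quantifying age- and body-mass-index-based homophily in
*directed* online social networks (follower → followee ties), separately
for women's and men's same-gender ties, and for asking whether trait
similarity predicts whether a follow is reciprocated. It is aimed at
researchers in social network analysis and behavioral ecology working with
profile + edge-list data such as the public Pokec snapshot.

## What it computes

* **Cleaning** — plausibility filters for self-reported age (12–59 y),
  height (140–200 cm), mass (10–200 kg) and derived BMI (15–35 kg/m²),
  and a young-adult analysis window (15–32 y). BMI is always recomputed
  as mass/(height/100)².
* **Assortativity** — Newman's numeric assortativity coefficient *r* on
  the directed graph: the Pearson correlation of the attribute values over
  all (follower, followee) edge pairs; *r* ∈ [−1, 1], 0 = no segregation.
  Also conditioned on intervals of the other trait to control for the
  age–BMI correlation.
* **Chance level** — a degree-class null model: the (gender, age, BMI)
  bundles are permuted among nodes with identical (in-degree, out-degree),
  keeping the tie structure intact; the observed *r* is compared with the
  95% interval of the shuffled ensemble (100 replicates by default).
* **Dyadic mixed models** — on the long-format dyad table (one row per
  ordered same-gender tie): linear mixed models of the followee's
  standardized trait on the follower's (random intercept per follower,
  full factorial with dyad gender and the other-trait difference), and a
  binomial-logit mixed model of tie reciprocity on the standardized
  absolute age and BMI differences. Per-gender simple slopes β and
  predicted-probability contrasts (e.g. reciprocity at |ΔBMI| = 0 vs 10)
  are derived from the fits.
* **Synthetic networks** — a generator with two gender groups, distinct
  BMI distributions, an age–BMI association stronger in men, homophilous
  tie formation, and difference-dependent reciprocation, so the whole
  chain can be validated against known ground truth.

## Worked example

The package ships a 200-node synthetic fixture in the Pokec snapshot
dialect (tab-separated profiles with a free-text body field; two-column
edge list):

```r
library(sociomix)
fix <- function(f) system.file("extdata", "synthetic_pokec", f,
                               package = "sociomix")
cfg <- analysis_config(
  profiles      = fix("synthetic-pokec-profiles.txt"),
  relationships = fix("synthetic-pokec-relationships.txt"),
  dialect = "pokec", n_reps = 100, seed = 1)
report <- run_full_analysis(cfg, quiet = TRUE)
print(report)
#> <analysis_report>
#>   users: 200 | complete: 99.5%
#>   woman: r_age = 0.691, r_bmi = 0.357 (232 edges)
#>   man: r_age = 0.693, r_bmi = 0.551 (564 edges)
#>   null woman_age: mean 0.203 [0.183, 0.224] (observed differs)
#>   null woman_bmi: mean 0.022 [0.002, 0.042] (observed differs)
#>   null man_age: mean 0.058 [0.044, 0.071] (observed differs)
#>   null man_bmi: mean 0.043 [0.032, 0.055] (observed differs)
#>   age_similarity slopes: women 0.731, men 0.756 (interaction p = 0.723)
#>   bmi_similarity slopes: women 0.358, men 0.610 (interaction p = 0.00646)
#>   reciprocity slopes: women 0.014, men -0.078 (interaction p = 0.566)
#>   reciprocity contrast (woman): 0.564 -> 0.764 (20.0 pp)
#>   reciprocity contrast (man): 0.627 -> 0.534 (-9.3 pp)
```

Reading the output: both genders' ties are strongly age-assortative
(r ≈ 0.69) and BMI-assortative, and in every case the observed coefficient
lies outside the 95% band of the degree-class shuffle — the segregation is
not explained by who is how active. The similarity-model slopes are the
regression counterparts of the assortativity coefficients (with standard
errors, so genders can be compared); the reciprocity rows give the change
in predicted reciprocation probability as the BMI difference grows from 0
to 10 kg/m². At 200 nodes the dyadic estimates are noisy and the null is
conservative (most degree classes are singletons, so shuffles move few
attributes); run the generator at a few thousand nodes for stable values.

To analyse the real Pokec snapshot, point `profiles`/`relationships` at
`soc-pokec-profiles.txt` and `soc-pokec-relationships.txt` with
`dialect = "pokec"`. Generic TSV/CSV node tables with an
id/gender/age/height/mass header are read with `dialect = "generic"`.
`inst/scripts/run-analysis.R` wraps the same chain for shell use.

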