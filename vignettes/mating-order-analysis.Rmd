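---
title: "Partitioning paternity variance between mating order and repetitive mating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning paternity variance between mating order and repetitive mating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matequeue)
```

## The problem

In many insects the last male to mate a female sires a disproportionate
share of her subsequent offspring (last-male sperm precedence). In freely
mating groups, where each female may mate several males repeatedly over
several days, a male's paternity share can therefore be shaped by at least
two behavioural routes: *where he sits in each female's mating queue*
(mating order) and *how often he re-mates with the same females*
(repetitive mating), which raises his ejaculate representation without
necessarily changing his queue position.

`matequeue` analyses the standard group design for this question: replicate
vials of four males and four females observed for a few hours on each of
four consecutive days, with every copulation logged. One focal male per
vial is wild-type for a recessive eye-colour marker (*spa*) carried by all
rivals and females, so offspring eye phenotype assigns paternity to "focal"
versus "any rival". Between sessions each female lays eggs for 20 h, giving
one marker-split offspring count per female per day. Group composition is
manipulated through larval density, which sets adult body size: vials vary
female size (F), male size (M) or both (FM), in homogeneous (Hom) or mixed
(Het) size compositions.

## Scores

All per-vial statistics condition on **eligible** females: those that mated
the focal male at least once *and* at least one rival, since only their
offspring put the focal male under sperm competition.

**Competition window.** For each eligible female the window opens on the
earliest day by whose end she has mated both the focal male and a rival
(e.g. focal on day 1, rival on day 3: the window is days 3–4). Offspring
batches laid before the window are excluded from paternity.

**Paternity share (PS).** By default the pooled ratio
$\mathrm{PS} = \sum_i wt_i \,/\, \sum_i (wt_i + spa_i)$ over all
contributing female-days, where $wt$ counts wild-type (focal-sired)
offspring. The printed-formula notation for this quantity is ambiguous
between pooling counts and averaging per-female proportions, so
`pooling = "per_female_mean"` is provided; pooling is the default because
the formula sums counts.

**Mating-order index.** For each eligible female and each day from her
window start to day 4, an indicator scores 1 if the focal male was the last
to have mated her by the end of that day (within-day ties resolved by the
copulation rank `seq`). The last male *carries forward*: a female who stops
mating keeps scoring her final mate on the remaining days. The index is the
mean indicator pooled over all scored female-days with equal weight, not a
mean of per-female means — female series have unequal lengths, and pooling
matches the "across all females and across all days" construction. Days
before the window start contribute no score by default (sperm competition
is not yet possible); `prestart = "from_first"` scores from the female's
first mating instead, for sensitivity analyses.

**Repetitive matings.** The sum over eligible females of the focal male's
matings with each. The default counts *all* such matings
(`convention = "total"`); `"rematings"` subtracts the first mating with
each partner. Both are exposed because the verbal definition ("the sum of
the number of matings … with each of his female mating partners") supports
the total while the word "re-mating" suggests the excess.

Two fecundity covariates are computed: the mean total offspring of all four
females in the vial (`group_mean_fecundity`) and of the focal male's
eligible mates only (`mate_mean_fecundity`). The variance partition
controls for mate fecundity by default (that is the stated covariate of the
paternity model) with the group mean available as an option, since the
composition GLMs control for group fecundity instead.

## Commonality analysis

The variance partition fits the linear model

$$\mathrm{PS} \sim \text{order}_z + \text{repeat}_z + \text{fecundity}$$

with order and repeat standardized (mean 0, sd 1, denominator $n-1$) within
the rows being analysed, and decomposes its $R^2$ by commonality analysis:
for every non-empty subset $S$ of predictors a coefficient $C(S)$ such that
for every subset $W$,

$$R^2(W) \;=\; \sum_{S \,:\, S \cap W \neq \emptyset} C(S).$$

Singleton coefficients are the predictors' *unique* contributions; larger
subsets carry *common* (shared) variance. The implementation enumerates all
$2^k-1$ subset $R^2$ values (OLS via QR, guarded at $k \le 15$) and solves
the system in closed form by Möbius inversion,
$C(S) = \sum_{T \subseteq S} (-1)^{|S|-|T|+1} R^2(P \setminus T)$.
The defining system is re-checked to $10^{-10}$ on every call, negative
coefficients (suppression) are reported verbatim with a warning, and a
rank-deficient design raises an error rather than silently dropping a
predictor.

**Reporting buckets.** Published three-column summaries of this analysis
("mating order", "repetitive mating", "remaining") do not state how the
full commonality output was collapsed. The package's default rule is
explicit: the order and repeat buckets are those predictors' unique
coefficients and *remaining* absorbs every common component plus the
covariate's unique variance, so the three buckets always sum to the total
$R^2$. An alternative rule (`rule = "split_common"`) divides each common
component equally among its members. Per-treatment tables subset vials by
(experiment, social, focal size) before fitting, with a minimum of six
usable vials (predictors + 3) per cell.

## Composition models

Mating order is modelled with a quasi-binomial GLM (the index is a
proportion of scored female-days; the quasi family estimates a dispersion
parameter instead of assuming binomial noise) and repetitive matings with a
quasi-Poisson GLM, each on `social * focal_size` plus group fecundity,
dropping a factor that does not vary in the experiment at hand. Terms are
tested with F statistics on dispersion-scaled deviance differences, which
is the appropriate test under quasi-likelihood. The index enters unweighted
by default because per-vial denominators (scored female-days) vary; an
option weights by them.

Backward model selection uses AIC. AIC is undefined under quasi-likelihood,
so the criterion is computed on the paired conventional fit (binomial or
Poisson refit of the same linear predictor) while the returned model keeps
the quasi family; QAIC (deviance scaled by the full model's dispersion) is
available as an option. Marginality is respected, so interactions leave the
model before their main effects.

Where a range-based sequential post-hoc would traditionally follow a
significant composition effect, the package runs all pairwise contrasts of
cell means with Holm correction (`pairwise_contrasts()`), triggered by an
omnibus p-value below 0.07 by default so that marginally non-significant
effects can also be inspected.

The interaction analysis fits, per experiment, linear models of paternity
share on each standardized score interacting with the composition factors.
Where only `social` varies the model is `score * social`; where focal size
varies too, both two-way interactions `score * social + score * focal_size`
enter (the three-way interaction is left out: with 30–40 vials per
experiment it is poorly estimable and was not part of the design's
questions). The median-split summary then splits each group at its median
order index (ties to the "≤ median" side, matching the ≤/> labels) and
reports mean paternity share, its standard error ($sd/\sqrt{n}$) and $n$
per side.

The assortative-mating check uses vials in which both female size classes
are present, with the focal male's mating count per female size class as
response: `count ~ female_size` for the female-size experiment and
`count ~ female_size * focal_size` where focal size varies. This layout is
the package's own construction — the original verbal description ("number
of matings between … focal male and females of the same body size") does
not fix a response layout — and it makes "no preference" an exact null.

## The simulator

`simulate_experiment()` generates data with exactly the structure the
analysis assumes, so every stage can be validated by parameter recovery
without any deposited data.

Each vial runs `days = 4` sessions of `slots_per_session = 12` courtship
opportunities. In a slot a male is drawn with probability proportional to
his size weight (`male_weight_large = 1.5`, `male_weight_small = 1`) and a
female uniformly; she accepts with `virgin_receptivity = 0.7` if unmated,
otherwise `remated_receptivity_base = 0.18`, further multiplied by
`receptivity_size_mod = 0.6` when a small male courts a mated large female
(mated females resist, and large mated females resist small males most).
These defaults were chosen once to mimic the study system: they yield on
the order of 10–12 matings per vial (≈ 2–3 per female) over the four days,
most females polyandrous, with a mild large-male advantage — the regime the
design presumes. They are inputs to the generative model, not fitted
quantities.

**Sperm displacement.** Each female carries a vector of stored-sperm
shares. A mating gives the male share `p_disp` and scales all prior shares
by `1 - p_disp`; shares always sum to 1. `p_disp = 1` is complete last-male
precedence; the default 0.85 sits in the strong-precedence range reported
for *Drosophila*-type systems (the true value for any one population is a
free parameter, which is precisely why it is a knob). Displacement acts on
*proportional representation* rather than absolute sperm counts — the
simplest generative mechanism consistent with proportion-based paternity —
and the alternative `displacement = "fair_raffle"` mode gives every mating
an equal raffle share (paternity proportional to mating counts), creating
the low-precedence contrast used in recovery tests. After each session
every mated female lays `Poisson(fecundity_mean = 20)` offspring whose
sires are multinomial draws from her *current* shares, matching the 20-h
laying interval that follows each session; virgin females contribute no
offspring.

Treatment compositions mirror the study design: F varies female size
(all-large, all-small, 2+2) under all-large males; M varies male size under
all-large females, with heterogeneous-male vials containing one rival of
the focal male's size and two males of the other size, and focal males
large in half of the heterogeneous replicates and small in the other half;
FM varies both. Default replication is 20 heterogeneous and 10 of each
homogeneous treatment (40 vials per experiment).

**What the simulator does not emulate.** Sperm ageing and death, seminal
fluid effects on oviposition and receptivity, cryptic female choice,
time-decaying (rather than two-state) receptivity, mating-duration
constraints, and any physiological consequence of larval density beyond
the size labels. Passing recovery tests therefore demonstrates that the
*pipeline* correctly recovers structure from data generated under these
assumptions — not that real groups satisfy them.

## Numerical and degenerate-input conventions

* Standardization uses the $n-1$ sd denominator everywhere and refuses
  zero-variance input with a named error.
* Paternity share and order index are `NA` (a typed "no competition data"
  value, never an exception) when a vial has no eligible females or no
  window offspring; model functions drop such vials and refuse to fit when
  fewer than four usable vials or a constant response remain.
* Within-day mating order is a rank (`seq`), not a timestamp: rank order is
  the minimal sufficient statistic for every downstream computation, and no
  time format is assumed. Days are numbered from 1.
* Duplicated predictor columns raise a singularity error; commonality
  coefficients are checked against their defining system to $10^{-10}$ on
  every call.
* All randomness flows through R's RNG: a fixed seed plus a fixed config
  makes the simulate–score–partition pipeline byte-identical across runs.

## Problem sizes used in the shipped tests

The test suite validates calibration and recovery at sizes chosen to make
Monte Carlo error small relative to the assertion margins: the type-I error
of the quasi-GLM size tests uses 500 null replicates of a 30-vial
male-size experiment (rejection rate asserted inside the binomial 95% band
around 0.05); power uses 200 replicates at a 2:1 large-male courtship
advantage; the variance-partition recovery sweep uses 100 replicates of a
40-vial FM experiment at each displacement setting (fair raffle, 0.8,
0.95); the displacement-determinism property uses 15–20 replicates at high
fecundity.

## A worked run

```{r example, eval = FALSE}
d <- simulate_experiment("FM", n_het = 20, n_hom = 10, seed = 2024,
                         params = sim_params(p_disp = 0.95))
scores <- focal_scores(d)
partition_table(scores, by = "experiment")
fit_order_glm(scores)
median_split(scores)
```

With strong simulated precedence the mating-order bucket dominates the
partition (typically well over half of a total $R^2$ around 0.8–0.95) and
the repetitive-mating bucket is near zero — the same qualitative picture
the method was designed to quantify.

## Known limitations

* Rival males share one marker, so only focal paternity is measurable;
  nothing here estimates rival-level precedence.
* The commonality buckets are a reporting convention; with correlated
  predictors the "remaining" bucket mixes shared behavioural variance with
  covariate effects, and negative (suppression) components can make
  individual buckets exceed the total.
* Quasi-GLM F-tests are approximate for a proportion response with varying
  denominators: vials contribute different numbers of scored female-days,
  and the pooled dispersion estimate makes the term tests mildly
  conservative at the study's design size. Calibration is assessed by
  simulation in the test suite, not proved.
* At the study's replication (30 vials, size contrasted within only the
  heterogeneous third of them), the per-vial order index is too noisy for a
  moderate (2:1) mating-advantage manipulation to be reliably detectable;
  the composition GLMs are faithful to the design rather than powerful.
* The backward-selection criterion computed on the paired non-quasi fit
  ignores overdispersion unless QAIC is requested.
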