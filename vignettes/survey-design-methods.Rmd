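---
title: "Methods: planning, drawing and evaluating a two-stage household survey"
author: "hhsurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: planning, drawing and evaluating a two-stage household survey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hhsurvey)
```

`hhsurvey` implements the standard methodology of municipal household health
surveys that combine age–sex stratified sample-size planning with two-stage
cluster sampling, probability proportional to size (PPS) at the first stage
and a fixed sampling fraction at the second.  This vignette is the package's
account of that methodology: the model behind each stage, the parameters
that matter, the numerical conventions, and what the synthetic-data
machinery does and does not demonstrate.

## 1. Sample-size planning

The planning input is a reference population stratified by sex and seven
age bands (`r paste(age_groups(), collapse = ", ")` years), plus the
municipal total of private households $D$.  For stratum $g$ with population
$N_g$, the person/household ratio

$$ r_g = N_g / D $$

is the expected number of stratum-$g$ individuals a sampled household
contributes.  To expect at least $m$ individuals in every stratum
(default $m = 30$, the usual normal-approximation floor for the sampling
distribution of a mean), each stratum requires

$$ h_g = \operatorname{round}(m \cdot D / N_g) $$

households, and the base sample is the worst case over the 14 strata,
$n_0 = \max_g h_g$ — in practice driven by the scarcest group (young
children of one sex).  Anticipating a response rate $R$ (default 0.90),
the field sample is $n = \lfloor n_0 / R \rfloor$.

### Rounding conventions

The published planning tables this methodology comes from do not state
their rounding rules, so the package fixes a convention and applies it
everywhere:

* $h_g$ and the expected individuals $e_g = \operatorname{round}(r_g n_0)$
  use *round half up* on the **unrounded** ratio.  Round-to-nearest (rather
  than ceiling) is what reproduces reference tables cell by cell; for
  example a requirement of 554.19 households is reported as 554, not 555.
* The non-response inflation **truncates**: $\lfloor 578/0.9 \rfloor = 642$
  and $\lfloor 620/0.9 \rfloor = 688$.  Rounding to nearest would give 689
  in the second case; truncation is the convention consistent with
  reference values.
* A consequence worth knowing: because $h_g$ is itself rounded, the
  realized expectation $r_g n_0$ for the limiting stratum can in principle
  fall a hair below $m$ (when the requirement was rounded *down*).
  `sample_plan()` warns if and only if that actually happens.

`round_half_up` (commercial rounding) is used instead of base `round()`
because banker's rounding at exact .5 boundaries would silently disagree
with spreadsheet-produced planning tables.

### Precision profiles

`precision_profile()` reports, for a stratum of size $n$ and an anticipated
proportion $p$, the binomial standard error $se = \sqrt{p(1-p)/n}$, the 95%
interval $100(p \pm 1.96\,se)$ and the coefficient of variation
$Cv\hat{p} = 100\,se/p$.  Conventions:

* The default grid is $p = 10\%, 20\%, \dots, 70\%$ — a coarse ten-point
  grid over the range in which household-survey prevalences typically fall;
  $p = 50\%$ is the conservative worst case ($Cv = 100/\sqrt{n}$ exactly).
* $z = 1.96$ and **no finite-population correction** by default; this is
  what published planning tables use.
* The closed form is the default; a Monte-Carlo mode (binomial resampling,
  default 10,000 replicates) is provided because such tables are sometimes
  described as "simulations" — the two agree within Monte-Carlo error, so
  either reading of that word yields the same numbers.

## 2. PSU construction

Census tracts — the smallest area units with published counts, about 300
households / 1,000 inhabitants each — are turned into primary sampling
units whose sizes are homogeneous: the coefficient of variation of PSU
household counts (population SD over mean) must not exceed `cv_max`
(default 0.10).  Homogeneous sizes make a PPS draw nearly equiprobable
*across PSUs* and stabilize realized sample sizes.

The constraint leaves the construction algorithm open; the package uses a
deliberately simple iterative rule in tract-code order (code order is kept
throughout so the systematic draw spreads over the whole municipality):

1. Let $T$ be the current mean unit size.  Any *single-tract* unit larger
   than $1.5T$ is split into $\lceil \text{size}/T \rceil$ consecutive
   fractions with near-equal whole-household counts (largest remainder —
   never fractional households; each fraction is a contiguous run
   `hh_from:hh_to` of the tract's household listing).
2. Any unit smaller than $0.5T$ is merged with its code-order neighbour.
3. Repeat until the CV constraint holds or a full pass changes nothing; a
   stalled pass raises an error carrying the achieved CV and the offending
   sizes rather than silently returning a non-compliant frame.

The split/merge thresholds ($1.5T$, $0.5T$) are the natural hysteresis
band: any unit inside $[0.5T, 1.5T]$ is closer to the mean than to 0 or
$2T$, so moving it cannot reduce dispersion under this vocabulary of moves.
Realistic tract-size dispersion (Poisson around 300, coefficient of
variation $\approx 1/\sqrt{300} \approx 5.8\%$) already satisfies the 10%
constraint, so splits and merges only fire on genuinely outsized or
undersized tracts.  No spatial information is used beyond code adjacency.

## 3. The two-stage draw

**First stage.**  Household counts $M_i$ are cumulated in code order; the
interval is $I = \sum M_i / a$; a uniform start $U \in [0, I)$ selects the
PSUs containing $U, U+I, \dots, U+(a-1)I$.  The random start is a *real*
number (fractional-interval systematic sampling), so $a$ need not divide
the total and first-stage inclusion probabilities are exactly
$\pi_i = a M_i / \sum M_i$.  A PSU larger than $I$ is a certainty unit (it
can be hit twice); the package warns and caps $\pi_i$ at 1 — with the size
CV constraint of §2 this does not arise in practice.

**Second stage.**  The design fixes the within-PSU fraction at $b / M_i$.
Applied to the updated field listing $M_i'$, the realized take is

$$ b_i = \operatorname{round}(b \, M_i' / M_i), $$

so the sample grows (or shrinks) with the sector while the product of the
stage fractions stays fixed:

$$ \pi_i \cdot \frac{b}{M_i} = \frac{a M_i}{\sum M_i} \cdot \frac{b}{M_i}
   = \frac{ab}{\sum M_i} = f $$

— the global sampling fraction, identical for every household: the design
is *self-weighting* with design weight $1/f$.  When $M_i' \ne M_i$ the
rounding of $b_i$ perturbs equiprobability slightly; the package records
the realized per-household probabilities (`p_incl`) so the user can
reweight, while the default estimator keeps the self-weights, which is the
standard field practice.

$b$ is a design input, conventionally $\operatorname{round}(n / a)$ for a
planned household sample $n$ spread over $a$ PSUs
(`experiment_config(n_target = ...)` applies exactly that default).

## 4. Fieldwork and non-response

The contact model has three parameters: `p_absent_visit` (a visit finds
nobody home), `p_refusal` (the residents refuse at the first successful
contact) and `max_attempts` (default 3 — the customary protocol of
returning on different days and times before declaring the household
closed).  Outcome probabilities are closed-form:

$$ P(\text{absence}) = p_{abs}^{3}, \qquad
   P(\text{refusal}) = (1 - p_{abs}^{3})\, p_{ref}, \qquad
   P(\text{interview}) = (1 - p_{abs}^{3})(1 - p_{ref}). $$

Refusal is resolved once, at the first contact — the model does not allow
later persuasion of a refusing household, and a closed household is not
distinguished from an absent one (both are non-response by absence).
Non-response rates are reported as percentages of the drawn sample $X$:
NRR-Total $= 100\,x/X$ with the refusal/absence split summing to the total
exactly before rounding.

## 5. Design-based estimation

`estimate_proportion()` computes the weighted ratio estimate
$\hat p = \sum w y / \sum w$ and its Taylor-linearized variance under the
**ultimate-cluster** (first-stage-with-replacement) approximation: with PSU
totals $Y_j = \sum_{k \in j} w_k y_k$, $W_j = \sum_{k \in j} w_k$ and
$W = \sum_j W_j$, the linearized residuals are
$u_j = (Y_j - \hat p W_j) / W$ and

$$ \widehat{V}(\hat p) = \frac{a}{a-1} \sum_{j=1}^{a} (u_j - \bar u)^2 . $$

Choices and their rationale:

* **With replacement, no fpc, no joint inclusion probabilities.**  This is
  the standard variance for self-weighting systematic-PPS designs and what
  production survey software computes.  It over-states the variance when
  the first-stage sampling fraction $a/A$ is large; with municipal frames
  ($A$ in the hundreds) the bias is negligible, and conservative otherwise.
* **Domain estimation keeps every PSU**: a PSU without domain members
  contributes a zero residual but stays in the count $a$ — dropping it
  would understate the variance of subpopulation estimates.
* **CI critical value**: $t_{a-1}$ by default ($a$ = PSUs, the effective
  degrees of freedom of the between-cluster variance), with a `ci = "z"`
  option; intervals are truncated to $[0, 1]$.
* **Degenerate cases**: $\hat p \in \{0, 1\}$ flags $Cv$/deff as undefined
  with a warning; fewer than two PSUs containing domain members is an
  error (the variance does not exist), as is an empty domain.

The precision diagnostics follow the conventional thresholds:
$Cv\hat p = 100\,se/\hat p < 20\%$ counts as precise;
$\text{deff} = \widehat V / (\hat p(1-\hat p)/n) \le 1.5$ as an efficient
design, with $\text{deff} < 2$ the softer bound also tallied
(`classify_precision()` reports all three counts).  The SRS denominator
uses the with-replacement binomial variance at the *unweighted* respondent
count $n$, matching the self-weighting setting.

### Predictive mean matching

Indicators with missing values can be completed by PMM before estimation:
a linear model on the complete rows yields predicted means; each missing
row receives the observed value of one of its $k = 5$ nearest donors
(distance on the predicted mean; the donor drawn uniformly, seed
controlled).  Five donors is the de-facto standard: small enough to match
locally, large enough to propagate donor variability.  Imputed values come
from the observed support, so a binary indicator stays binary and the
self-weighting design is untouched.  The function *refuses* to impute when
more than 20% of the target is missing — beyond that the matching model,
not the data, would drive the estimates.

## 6. The synthetic-frame generator

The generator exists so the whole pipeline can be exercised and validated
without confidential microdata.  It emulates the features the design
actually interacts with:

* **Tracts**: household counts Poisson around
  `mean_households_per_tract = 300`, truncated below at 50 — realistic
  dispersion (CV ≈ 6%) without degenerate mini-tracts.  The scale mirrors
  the census-tract convention of ~300 households / ~1,000 inhabitants.
* **Households**: sizes $1 + \text{Poisson}(\mu - 1)$ with
  $\mu = 10/3$ persons, so a 300-household tract holds about 1,000 people.
* **Persons**: assigned independently to the 14 sex × age strata with
  shares defaulting to the packaged urban census composition
  (`default_stratum_shares()`).  Ages are generated as categories directly;
  the design never uses continuous age.
* **Indicators**: binary, with prevalence either global or per stratum,
  and a *tract-level* random effect producing a chosen intra-cluster
  correlation $\rho$.  The mechanism is the beta-binomial construction:
  tract prevalence $p_t = F^{-1}_{\text{Beta}(\alpha,\beta)}(q_t)$ with
  $\alpha = p(1-\rho)/\rho$, $\beta = (1-p)(1-\rho)/\rho$ and one uniform
  quantile $q_t$ per tract.  This yields the target within-tract
  correlation **exactly** (no numerical calibration step), and sharing
  $q_t$ across domains makes a high-prevalence tract high for every
  domain, as real area effects are.  $\rho = 0$ degenerates to constant
  prevalence.  Missingness is completely at random.

What the generator deliberately does **not** emulate: household-level
clustering beyond the tract effect (members of one household are
conditionally independent), age–sex differences in household composition,
informative missingness, spatial geometry, and any correlation between
tract size and prevalence.  Consequently the validation results below
demonstrate the *internal consistency* of the machinery — estimator
against its oracle, deff against Kish's $1+(\bar b-1)\rho$, coverage at
nominal level — not the behaviour of any real population, where
missingness may be informative and within-household correlation adds a
second clustering level.

## 7. Validation design and problem sizes

The test suite validates each stage against an independent oracle, at
problem sizes chosen to make Monte-Carlo error small relative to the
tolerance being asserted while keeping the default run fast:

* Linearized variance vs a term-by-term brute-force evaluation on ≤20-row
  fixtures, to $10^{-12}$ relative.
* 95% CI coverage over 500 replicate surveys ($a = 30$ of 60 PSUs,
  $b = 12$, $\rho = 0$): expected in $[0.93, 0.97]$.
* Mean deff vs Kish at $\rho \in \{0, 0.02, 0.05\}$ with equal takes
  ($b = 20$, one-person households), 200 replicates per level, ±15%.  The
  frame holds 300 PSUs so the first-stage fraction (10%) keeps the
  with-replacement approximation honest; with $a/A = 1/2$ the deliberate
  no-fpc conservatism becomes visible, which is a property of the
  estimator, not a defect of the generator.
* Household inclusion frequencies over 20,000 replicate draws on a
  ~2,000-household frame: each household's frequency is compared with $f$
  at 3 binomial SEs.  With 2,000 parallel comparisons ≈0.27% are expected
  outside 3 SEs by chance, so the assertion is on the exceedance *rate*
  (≤1%) and an absolute 5-SE cap, the statistically correct reading of a
  per-household check.
* Fieldwork outcome frequencies vs the closed form at $n = 10{,}000$,
  3 SEs.
* The generator's ICC against a one-way ANOVA (moment) estimator, ±0.02.

## 8. Known limitations

* The PSU builder's move vocabulary (split oversized single tracts, merge
  undersized neighbours) cannot fix every pathological frame — e.g. two
  mid-sized unequal tracts that neither move touches; it fails loudly with
  diagnostics rather than approximating.
* Variance estimation offers only the ultimate-cluster estimator: no
  joint-inclusion (Horvitz–Thompson–Yates–Grundy) alternative, no
  successive-difference estimator for systematic ordering effects.
* PMM is single imputation: it preserves point estimates and support but
  does not propagate imputation uncertainty into the variance (no multiple
  imputation combining).
* Frame growth ($M_i' \ne M_i$) is handled by the fixed-fraction rule; the
  package reports realized inclusion probabilities but does not implement
  a full reweighting estimator for severely aged frames.
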