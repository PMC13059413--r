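---
title: "Mapping informal leadership from advice-seeking networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping informal leadership from advice-seeking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`leadmap` operationalizes informal leadership as the joint position of an
actor on two axes. *Leadership-as-Imagined* (LAI) is self-perceived: each
respondent rates eight statements on a 5-point Likert scale, two statements
per leadership style (relational, transformational, adaptive, resilient).
*Leadership-as-Done* (LAD) is enacted: it is read off the directed
advice-seeking network, in which a tie $j \to k$ with frequency $x_{jk}$
records that actor $j$ seeks advice from actor $k$.

Four centralities serve as style proxies. In-degree (the number of distinct
nominators) stands for transformational leadership: being sought out as a
trusted advisor. Betweenness (the share of directed geodesics between other
pairs passing through an actor) stands for relational leadership: brokering
information between parts of the service. Out-closeness stands for adaptive
leadership: the efficiency of reaching everyone else, i.e. disseminating.
In-closeness stands for resilient leadership: the efficiency of being
reached, i.e. receiving. These proxies are approximations — a centrality
cannot capture, for example, how well the received information is used — and
the package makes no stronger claim for them.

Each raw centrality is mapped affinely onto the Likert range,
$n = 1 + 4\,(x - \min x)/(\max x - \min x)$, so the four metrics become
commensurate with the self-rating items. The composite score for actor $k$
is then

$$\mathrm{LS}_k = \sum_{i=1}^{4} w_i\, n_{ik},$$

where the style weights $w_i$ come from the preceptors: each ranks the four
styles from 1 (most important) to 4 (ties allowed), ranks are mapped through
the reciprocal values $1{.}00, 0{.}50, 0{.}33, 0{.}25$, summed per style and
normalized to $\sum_i w_i = 1$. The mapping deliberately uses the
two-decimal constants (0.33, not 1/3): the elicitation rule is defined on
those printed values, and only under them do the aggregated per-style sums
reproduce their published totals. The LAI score is the same weighted sum
applied to the per-style means of the two items. Since the weights are a
convex combination, both scores inherit the $[1, 5]$ range of their inputs.
The dispersion reported next to either score is the sample standard
deviation ($n-1$ denominator) of the four weighted components
$w_i \times$ (metric or style mean); it measures how evenly an actor's
leadership is spread across styles. That interpretation of the published
parenthetical dispersions is an inference, but it reproduces them to two
decimals for every reconstructable row, including the fixed point of an
all-maximum respondent (LAI 5.00, SD 0.21).

Actors are classified by comparing each score to its sample mean over the
actors of the current network boundary; at-or-above counts as "high"
(matching the published $\geq$ convention). High/high is an *established*
leader, low/high *humble*, high/low *aspirational*, low/low *latent*.

## Numerical and convention choices

**Binarized metrics by default.** Centralities are computed on the 0/1
adjacency: the in-degree narrative counts distinct nominators, and geodesic
metrics on frequency weights would need an unstated frequency-to-distance
transform. Frequency-weighted variants sit behind `weighted = TRUE`
(in-degree becomes the frequency sum; geodesics use distance = 1/frequency).
Note that min–max rescaling is invariant to any positive affine
pre-transform of a metric, so e.g. whether betweenness is pre-normalized by
$(n-1)(n-2)$ cannot change $n_{ik}$; the test suite asserts this.

**Harmonic closeness by default.** Advice networks routinely contain actors
with no incoming ties, for which classic closeness is undefined. Harmonic
closeness ($\frac{1}{n-1}\sum_u 1/d$, with $1/\infty = 0$) handles them
gracefully and is the default; a Freeman-style variant computed on the
reachable set and scaled by the reachable share (`variant = "freeman"`) is
available because desktop SNA packages differ in their convention.

**Degenerate rescaling.** A constant metric (e.g. betweenness on a complete
digraph) carries no ordering information; it is mapped to the mid-scale
value 3 with a prominent warning, keeping $\mathrm{LS}_k$ defined.

**Boundary-specific rescaling and cut-offs.** Restricting the network to
residents changes minima and maxima, so rescaling and both cut-offs are
recomputed within each boundary. Per-actor LAI values, by contrast, are
frozen across boundaries — self-perception does not depend on who else is in
the network. Style weights are an exogenous preceptor-elicited input and are
never re-derived for a restricted boundary.

**Ties and display.** Scores exactly at a cut-off classify as "high".
Internally everything is kept at full double precision; display columns
round half-up, percentages to one decimal and scores to two. Published
rescaled values appear to be rounded inconsistently at the second decimal
(e.g. a raw in-degree of 41 against a 0–46 range rescales to 4.5652, shown
as 4.56), so reconstruction checks use a ±0.01 display tolerance.

**Incomplete responses.** Actors with fewer than eight answered Likert items
stay in the network and LAD analysis but are flagged `lai_defined = FALSE`
and excluded from quadrant assignment, with a logged note. No imputation is
attempted. The Likert item-to-style map (items 1–2 relational, 3–4
transformational, 5–6 adaptive, 7–8 resilient) is a package convention;
datasets with a different instrument order should be re-mapped at ingest.

## The synthetic cohort generator

Real sociometric rosters are identifiable and typically restricted, so the
package includes a generative model that emulates the structure the analysis
assumes. Its defaults mirror the reference cohort: 68 actors (22 preceptors,
22 R1, 23 R2, 1 R3) and 19 preceptor rating responses.

The network is a planted-hub Bernoulli digraph: each ordered pair $(j, k)$
receives a tie with probability
$p_{jk} = p_0 \cdot m_h^{[k \text{ hub}]} \cdot m_p^{[k \text{ preceptor}]}$
capped at 0.99, with base rate $p_0 = 0.05$, hub multiplier $m_h = 8$ on a
planted 15% of actors, and a preceptor attraction $m_p = 1.5$ reflecting
advice flowing toward supervisors. A degree-sequence model was considered
and rejected: recovery experiments only need controllable centrality
separation, and the Bernoulli model is the simplest mechanism that yields a
dense, hub-centralized network of the kind observed in practice. Tie
frequencies are drawn independently of tie existence from a categorical
distribution skewed toward occasional advice (probabilities 0.35, 0.25,
0.20, 0.12, 0.08 for values 1–5), since no empirical frequency distribution
is available.

Self-perception is planted as a bimodal archetype: roughly half the actors
are *confident* responders (target mean near 4.5) and half *modest* (near
3.2), with item scores drawn around the target (SD 0.5) and clipped to 1–5.
The bimodality keeps the planted "high self-perceiver" flag well separated
from the sample-mean cut-off used downstream, which makes recovery
experiments interpretable. The `alignment_rho` parameter couples
self-perception to network position by reassigning complete item blocks to
actors through a Gaussian copula on ranks: at $\rho = 1$ the realized
self-rating means are an exactly monotone transform of centrality
propensity (the log odds of attracting ties), at $\rho = 0$ they are
independent. Rank coupling was chosen over an additive latent model because
it hits the target association without distributional assumptions. All
draws flow from a single seed, so a cohort is byte-reproducible.

Each generated actor carries a planted expected quadrant (hub × confident →
established, hub × modest → humble, non-hub × confident → aspirational,
otherwise latent), enabling end-to-end recovery experiments.

**What the generator does not emulate.** Real advice networks have
reciprocity, transitivity, team substructure and role-dependent *out*-degree
behaviour; the generator plants none of these — tie sources are
exchangeable, and hub status affects only incoming ties. Likert responses
have no item-specific difficulty or acquiescence bias, and rating responses
have no systematic rater effects beyond a modal ordering. Passing recovery
tests on this model therefore demonstrates that the pipeline's arithmetic
and classification logic are sound, not that the method separates leadership
archetypes in real cohorts.

A consequence worth stating plainly: because the planted mechanism touches
only incoming ties, out-closeness — 20–23% of the LAD weight under typical
weights — carries no hub signal at all, and in-closeness partially saturates
in a dense network where most actors are within two steps of each other.
The sample-mean LAD cut-off sits only about
$f_{\text{hub}} \times (\text{hub–non-hub LAD gap}) \approx 0.2$ above the
non-hub centre, which is comparable to the noise those uninformative
components contribute, so a substantial minority of non-hubs cross the
cut-off even at $\rho = 1$ and a strong hub multiplier. The planted-quadrant
recovery rate measured by `scripts/acceptance.R` (about 0.78 at the default
conditions, and below 0.9 across the whole plausible region of base rate and
multiplier) quantifies this ceiling; it is a property of the generative
model plus the sample-mean cut-off rule, not of the scoring arithmetic,
which the worked-example reconstructions pin down exactly.

## Problem sizes used in the test-suite experiments

Property checks run at sizes chosen to exercise the mathematics while
keeping the suite quick to iterate on: the betweenness engine is checked
against an exhaustive shortest-path-enumeration oracle on 200 random
digraphs of 3–6 nodes (where enumeration is exact), density calibration uses
50 seeds of the 68-actor default cohort, alignment monotonicity 20 seeds,
and archetype recovery 25 seeds. The full pipeline, including the boundary
sensitivity analysis, runs in well under a second per 68-actor cohort.

## Known limitations

* Centrality proxies capture accessibility and flow, not the quality of
  advice or decisions; the style mapping is theory-driven, not validated
  psychometrically here.
* Quadrant labels are a snapshot relative to *sample-mean* cut-offs: they
  are relative to the surveyed cohort and boundary, and should be read as
  formative rather than fixed classifications.
* The survey must be near-census: sociometric metrics degrade quickly with
  non-response, and the package does not model missing respondents (dropped
  rows are only counted and logged).
* The generator's recovery ceiling discussed above means synthetic
  validation of the *classification* step is conservative; studies wanting a
  sharper benchmark should plant source-side structure as well, which this
  model intentionally does not.
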