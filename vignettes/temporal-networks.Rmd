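---
title: "Methods: temporal structure of plant–visitor networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal structure of plant–visitor networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenonet)
```

This vignette is the package's own account of the methods it
implements: the models and their assumptions, the tunable parameters,
the numerical choices, and what the synthetic-data tests do and do not
demonstrate about real field data.

## The activity rule and its consequences

All network construction rests on one assumption: **a pair observed
interacting at least once interacts throughout its phenophase
overlap**. A species' phenophase is the closed interval of integer
days (the resolution of a field campaign is the field day) between its
first and last observed interaction; `length = end − start + 1`, so a
single observation gives a 1-day phenophase. The rule is deliberately
conservative: it hides single days of inactivity inside a phenophase,
and it makes link presence in any time window equivalent to a
non-empty three-way intersection of the window and the two
phenophases. Because phenophases and windows are intervals, Helly's
theorem in one dimension guarantees that the union of all 1-day slices
reconstructs the static network exactly — a property the test suite
checks, since it is the invariant that makes "static = accumulated
dynamical" meaningful.

Two consequences matter for interpretation. First, phenophases are
*observed* spans: sparse detection shortens them, so a season inferred
from thinned records is shorter than the true flowering season. The
package treats the observed season as the season (an explicit season
can be supplied and wins; records outside it are dropped with a
warning and counted). Second, the core/tail split — core if linkage
level $L > 2$, tail if $L \le 2$ — is a static, season-wide notion. In
daily slices a species can be momentarily partnerless; daily summaries
therefore classify by daily $L$ by default (a species' *realised* role
that day), flag $L = 0$ species as isolated-but-tail, and can instead
classify by season-wide $L$ via an option. This choice affects daily
tail counts, not the static analysis.

## Nestedness

`nodf()` is NODF: for every unordered pair of rows (and of columns)
with *strictly decreasing* marginal fill, the paired term is the
percentage of the sparser line's 1s shared with the denser line;
equal-fill pairs contribute exactly 0; the score is the mean over all
$\binom{R}{2} + \binom{C}{2}$ pairs. The implementation works from
fills directly, so it is invariant to input ordering; `sort_incidence()`
is display-only (descending $L$ with ties broken by increasing mean
partner $L$, remaining ties stable).

The significance test draws binary null matrices under one of two
classical models: *equiprobable* (every cell 1 with probability
fill$/(RC)$) and *degree-proportional* (cell $(i,j)$ 1 with probability
$(k_i/C + k_j/R)/2$), the latter the default because it is the
standard choice for pollination-network nestedness, conditioning the
null on the observed degree structure. Expected fill equals observed
fill in both. Null draws may contain empty lines; they are retained,
with empty/equal-fill pairs contributing 0 rather than erroring —
discarding degenerate draws would bias the null upward. The p-value
uses the add-one correction, so it is never exactly zero.

Two numerical caveats are documented rather than hidden. The plug-in
practice of deriving null margins from the observed matrix is mildly
anticonservative under the degree-proportional model when the observed
matrix is itself a null draw (its realised margins inherit sampling
noise); `nodf_test(..., margins_from = )` exposes the exchangeable
variant for calibration work. And communities whose core links are
placed with a *uniform* probability — as the synthetic generator does —
have homogeneous core degrees, so their nestedness signal against the
degree-conditioned null is real but modest (observed NODF exceeds the
null mean in ~95% of default seeds, reaching $p<0.05$ in ~70%), while
against the equiprobable null it is essentially always significant.

## Mid-domain test of tail segregation

For one core plant, the domain is $[\min \text{start}, \max \text{end}]$
over the phenophases of its tail visitors. Under the null, each range
keeps its length and its start is drawn uniformly from the feasible
integer positions — equivalent on a discrete domain to midpoint
sampling, and simpler to verify by enumeration. Randomly placed ranges
overlap most near the domain centre (the mid-domain geometric
constraint), so the null expectation is a mid-season richness peak.

The dispersion statistic $D$ of a curve is its mean daily absolute
deviation from the across-run mean curve. A *signed* mean difference
would be ~0 by construction (species-days are conserved in every run),
so the absolute form is what makes $D$ a usable
departure-from-expectation statistic. The empirical rank is
$1 + \#\{D_k < D_{emp}\}$ — ties rank low, a deliberate conservative
choice recorded in the output (`n_ties`) — and the percentile is
rank$/(n_{runs}+1)$. A percentile near 1 means stronger segregation
than the geometric null; near 0 means the observed curve hugs the null
mean unusually closely; both tails are reported and worth inspecting.
The default of 5000 runs follows standard practice for this kind of
randomisation and gives a percentile resolution of $2\times10^{-4}$.

## Time delays and temporal impossibility

The directed delay from species $s$ to $t$ is the difference of
phenophase starts, with two boundary rules: when the phenophases
overlap and $t$ started at or before $s$, the effect can pass as soon
as $s$ enters, so the delay is 1 day (the clock granularity — also the
floor when both start the same day); when the phenophases are disjoint
and $t$ ended before $s$ began, the connection is *temporally
impossible* — effects do not travel back in time within a season. This
yields exactly four classes for every ordered pair (overlap forward /
backward, gap forward, gap impossible), a total single-valued
classification with the duality impossible$(s,t) \iff$
forward-gap$(t,s)$, which the suite verifies exhaustively on a 10-day
lattice.

Direct delays are computed per link in both directions; the activity
rule forces linked phenophases to overlap, so direct pairs are never
gap-class. Indirect pairs are all remaining ordered pairs within the
giant component (component ties broken deterministically by smallest
member id), pooling unlinked plant–visitor pairs with the two 1-mode
pair types; percentages are reported pooled and per type. The
classification is by phenophase geometry alone — connectivity is
assumed through the giant component, and `coupler_chain()` exists as a
separate verification that a shortest chain of statically linked
species with no impossible step connects a pair; transmission delays
from coupler biology are deliberately ignored. Note that a
season-spanning coupler can make even a backwards-gap pair reachable
step-by-step: chain existence and end-to-end geometry are different
questions, and the reported percentages use the latter.

## The synthetic generator

The generator encodes the season structure the analysis assumes, sized
to a high-arctic study system: a 70-day season starting day 165; 34
plants (26 core + 8 tail) and 78 flower visitors (27 core + 51 tail),
matching a static relative tail length of ~0.65 for visitors and ~0.24
for plants; core phenophase lengths truncated-normal around 31 ± 8
days (the observed 30–33 day range) and tail lengths 6 ± 2 days (the
observed 4–8); tail starts burst-weighted (weight 0.7) into the last
third of the season, mirroring the observed late-season bursts of tail
visitors on core plants, with an early-burst option for the occasional
early bloomer; a core–core link probability of 0.30, chosen once so
that expected connectance lands near the observed ~11%; tail species
attach to at most 2 overlapping core partners (intended $L \le 2$);
and observation thinning at 0.5 expected visits per overlap day.
Core starts are drawn early-biased (a Beta(1,2) fraction of the
feasible offset) so long-phenophase species open the season yet still
cover its end — without that coverage late tail species could find no
partner.

Observation records are a per-day Poisson thinning of each pair's
overlap, with a guaranteed minimum of one record per intended pair so
that the observed and intended networks coincide exactly (the
round-trip invariant the tests rely on); the guarantee can be switched
off to study detection-induced phenophase shrinkage.

What passing tests on these communities show: the pipeline's
arithmetic, the stunting of the daily tail relative to the static tail,
and the directional asymmetry of temporal impossibility (late tails
cannot reach back to early cores). What they do not show: fidelity to
any real community's abundances, observer schedules, weather gaps, or
within-domain clustering of tail phenophases beyond the single burst —
so empirical effect sizes (NODF values, delay means, block percentages)
from real data will differ from the synthetic ones, and the package
reports them rather than targeting them.

## Problem sizes and determinism

The test suite and the acceptance script run at deliberate desk scale:
communities of ~112 species, NODF nulls at 200–1000 replicates,
mid-domain tests at 500–5000 runs, calibration sweeps over 50 seeds —
sizes at which every randomised result is stable to the asserted
tolerances within seconds to a few minutes. Every sampling stage takes
an explicit integer seed (`run_full_analysis()` derives and records
per-stage seeds in its provenance block), and identical configuration
plus seeds give byte-identical outputs.

## Known limitations

Phenophases are single intervals: a species with two genuinely
disjoint activity bouts is smoothed into one span by the activity
rule. Interaction counts are accepted but the network is binary, per
the ≥1-interaction rule, so the nestedness analysis is unweighted
(weighted NODF is out of scope). The mid-domain test conditions on the
observed range lengths; alternatives that resample lengths would ask a
different question. And the delay framework measures *potential*
delays from phenology — it is not a dynamical spreading model.
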