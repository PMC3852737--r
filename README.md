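# phenonet

Within a single flowering season, a plant–flower-visitor network is not
the static web its pooled interaction matrix suggests. Every species is
only present during its *phenophase* — the interval between its first
and last observed interaction — so the season is really a sequence of
small daily networks whose membership turns over continuously. phenonet
is for ecologists who have long-format daily visitation records (day,
plant, visitor) and want to quantify what that temporal structure does
to the classic static descriptors: nestedness and its specialist tail,
connectance, and the reachability of species by direct and indirect
effects.

## What it computes

**Networks under the activity rule.** A pair observed interacting at
least once is scored as interacting during its entire phenophase
overlap. `temporal_network()` infers phenophases and the season, builds
the static network, and classifies species into **core** (linkage level
*L* > 2) and **tail** (*L* ≤ 2). `slice_daily()` and
`aggregate_window()` cut the season into 1-day or *w*-day networks;
connectance is *C* = 100 · *I*/(*A·P*) for *I* links, *A* visitors and
*P* plants, and the relative tail length of a guild is *t*/(*c* + *t*).

**Nestedness.** `nodf()` implements NODF (paired overlap between lines
of strictly decreasing fill, averaged over all row and column pairs, in
[0, 100]); `nodf_test()` attaches a Monte Carlo p-value under an
equiprobable or degree-proportional binary null, with the add-one
correction `p = (1 + #{null ≥ obs})/(reps + 1)`.

**Mid-domain segregation.** For a core plant, `middomain_test()` asks
whether the phenophases of its tail visitors segregate non-randomly
across their joint time span ("domain"): each observed range is
re-placed uniformly at random, the dispersion statistic *D* is the mean
daily absolute deviation of a richness curve from the across-run mean
curve, and the observed *D* is ranked among the simulated ones
(percentile = rank/(runs + 1); near 1 ⇒ non-random segregation).

**Time delays.** For every ordered species pair the delay
*d* = start(target) − start(source) (floored at 1 day) is classified by
phenophase geometry into the four kinds of linkage: overlapping forward
or backward, gapped forward, or **temporally impossible** — the target
left the season before the source entered, so no effect can reach it.
`delay_table()` aggregates direct and indirect pairs into a summary
table;
`coupler_chain()` finds the shortest time-respecting chain of temporal
couplers between any two species.

**Synthetic seasons.** `simulate_phenonet()` generates a community with
the assumed structure — long-phenophase early core species, short-lived
tail species with a late-season burst, nested attachment of tails to
core partners — so the entire pipeline is testable without field data.

## Worked example

```r
library(phenonet)

sim <- simulate_phenonet(phenonet_config(seed = 1))
tn  <- temporal_network(sim$records)
tn
#> Temporal bipartite network
#>   season: days 167-229 (63 d)
#>   pollinators (A): 78  plants (P): 34  links (I): 313
#>   static connectance: 12%
#>   tail species (L<=2): 51 pollinators, 8 plants

round(attr(summary(tn, daily = TRUE), "means")[
  c("A", "P", "I", "tail_pollinators", "rtl_pollinators")], 2)
#>                A                P                I tail_pollinators
#>            16.32            13.59            73.03             5.13
#>  rtl_pollinators
#>             0.42
```

The static network carries 51 tail pollinators (relative tail length
0.65), but on an average day only ~5 of them are present and the daily
relative tail length drops to 0.42: the long specialist tail of the
static matrix is an accumulation artefact, a relay of ephemeral species
rather than a standing swarm.

```r
nodf_test(incidence_matrix(tn$static), n_reps = 1000, seed = 2)
#> NODF nestedness test (degree_proportional null, 1000 reps)
#>   NODF = 18.92   null mean = 15.65 (sd 1.21)   P = 0.006993

middomain_test(tn, "P02", n_runs = 5000, seed = 3)
#> Mid-domain randomisation test for core plant P02
#>   domain: days 217-229, 21 tail ranges, 5000 runs
#>   empirical D = 2.800  rank = 4948  percentile = 0.9894
#>   simulated D: mean 1.425  min 0.325  max 4.038
```

The static matrix is significantly nested, and the tail visitors of
plant `P02` are packed into a late burst that deviates from the
mid-domain null (percentile 0.99). `delay_table(tn)` then summarises
direct and indirect delays, including the share of indirect links that
are temporally impossible in each core/tail block.

`run_full_analysis(records, out_dir, seed = 1)` writes the whole report
bundle (summaries, nestedness, per-plant mid-domain tests, delay
records and table, provenance with all stage seeds) as CSV/JSON.

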