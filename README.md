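# trophamix

Quantitative analysis of trophallactic food sharing in ant colonies.

In many social insects, almost no individual feeds itself: a small set of
foragers loads liquid food into their crops ("social stomachs") at an
external source, and everyone else is fed through mouth-to-mouth transfers
(trophallaxis). `trophamix` takes a time-ordered table of such interactions
— who gave, who received, when, how much — and answers two questions: how
far does each forager's food spread, and how well do the different foragers'
collections *blend* inside individual crops?

## The model in brief

Label each unit of food by the forager `f ∈ F` that first collected it
("food types"). Assuming food mixes instantly inside a crop, every transfer
of volume `v` moves the fraction `v / V_donor` of the donor's crop,
type by type:

```
n'_recv(f) = n_recv(f) + (v / V_donor) · n_donor(f)
```

Propagating this update through the schedule yields, at every interaction
index, the joint distribution `P_{f,a} = n_{f,a} / Z` of types over
non-forager ants (`Z` is the food held by non-foragers). Blending is then
summarised by Shannon entropies:

* **types entropy** `H_types = −Σ_f P_f log P_f` — how evenly the foragers
  contributed; the ceiling on any mixing,
* **crop entropy** `h_mix^a = H(F | A = a)` — blending inside one crop,
* **mixing entropy** `H_mix = H(F|A) = Σ_a P_a · h_mix^a` — load-weighted
  blending over the colony; `H_mix ≤ H_types`, with equality only under
  perfect blending,
* **overall mixing entropy** `H_mix^overall = Σ_{a∈A∪F} (n_a/M) · h_mix^a
  = P_colony · H_mix` when forager crops are pure, which factorises global
  mixing into an accumulation term (`P_colony`, the satiation level) and a
  blending term.

Transfers themselves follow a stochastic rule: the realised fraction
`ṽ = v / v_max` of the feasible volume
`v_max = min(donor load, recipient free space)` is distributed as a
truncated exponential `p_δ(ṽ) = c_δ (1/δ) e^{−ṽ/δ}` on `[0, 1]`. The
package fits `δ` by maximum likelihood, and provides hybrid simulations
(replay the schedule under substituted rules: stochastic replay, maximal
mixing, maximal transfer, no secondary transfers) plus a deterministic
trade-off model exposing how `δ` balances fast dissemination against
thorough mixing.

## Worked example

```r
library(trophamix)

col   <- generate_colony(synthetic_colony_config(seed = 1))
trace <- track_provenance(col$schedule)
trace
#> provenance_trace 'synthetic': 700 events, 70 ants (5 foragers/types)
#>   final: M = 31.63, Z = 28.35, P_colony = 0.896

et <- entropy_trace(trace, normalize = TRUE)
tail(et, 1)[, c("H_types", "H_mix", "ratio")]
#>   H_types = 0.990, H_mix = 0.736, ratio = 0.743

fr <- compute_transfer_fractions(trace, col$capacities)
fit_delta_mle(fr$v_tilde)
#> transfer_rule_fit: delta = 0.2449 (c_delta = 1.017), n = 602 (+0 zero), mean v~ = 0.228

net <- community_stats(build_static_graph(col$schedule))
#> communities = 5, modularity = 0.165, transitivity = 0.239
```

Reading the numbers: after 700 interactions the colony holds 90% of the
collected food outside the forager crops (`P_colony = 0.896`); the five
foragers contributed almost evenly (`H_types = 0.99` of its maximum
`log 5`), yet crop-level blending reaches only 74% of that ceiling
(`ratio = 0.743`) — dissemination is near-complete while mixing stays
partial. The fitted `δ ≈ 0.24` says a typical interaction transfers about a
quarter of the feasible volume, and the contact graph shows no segregating
community structure (modularity 0.165), so it is the transfer rule, not the
network, that limits mixing. The synthetic generator draws its schedule from
exactly these mechanisms, so recovering the configured `δ = 0.26` and the
ground-truth provenance is a built-in correctness check.

Real schedules are read with `read_interactions()` (CSV with columns
`colony_id,time_s,donor,recipient,volume[,ambiguous]`, source feedings
marked by donor `SOURCE`) or `read_colony_workbook()` for spreadsheet
supplements with one sheet per colony.

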