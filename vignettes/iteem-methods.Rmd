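---
title: "Eco-evolutionary dynamics in interaction trait space: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eco-evolutionary dynamics in interaction trait space: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iteem)
```

## The model

`iteem` simulates a well-mixed community of individuals occupying `ns`
resource sites, each site sustaining at most one organism.  Organisms are
grouped into *strains*: sets of individuals with identical *interaction
traits*.  The trait of strain $\alpha$ is row $\alpha$ of the interaction
matrix $I$, where $I_{\alpha\beta} \in [0,1]$ is the probability that an
$\alpha$ individual survives a life-or-death encounter with a $\beta$
individual.  Interactions are reciprocal, $I_{\alpha\beta} +
I_{\beta\alpha} = 1$, with self-encounters at $I_{\alpha\alpha} = 0.5$.

A generation consists of `ns` sequential replication trials followed by one
death step:

1. an individual is drawn uniformly from all living individuals;
2. it replicates with probability $r_\alpha$;
3. the offspring mutates with probability $\mu$: its trait becomes the
   parental row plus independent $\mathcal N(0, m^2)$ perturbations
   (clipped to $[0,1]$; the complementary column entries are stored as
   exact complements so reciprocity is exact in floating point);
4. the offspring is dropped on a site drawn uniformly among *all* sites:
   an empty site is colonised, an occupied one is contested, the newborn
   killing the holder with probability $I_{\text{newborn},\text{holder}}$;
5. every newborn draws a lifespan from Poisson($\lambda$); the death step
   removes all individuals whose lifespan is reached.  $\lambda = \infty$
   disables the death step, so only contests kill.

Competitive ability is the unweighted mean interaction against the rest of
the community,
$C(T_\alpha) = \frac{1}{N_{st}-1} \sum_{\beta \ne \alpha} I_{\alpha\beta}$,
defined as 0 for a lone strain.  Because $C$ depends on the roster, $C$ and
$r$ are recomputed for every live strain whenever a strain is added or
removed; between roster changes they are constant, so this policy is exact
rather than an approximation.  Strains whose abundance reaches zero are
removed immediately and their matrix row/column deleted; retired strain
handles are never reused.

### The trade-off

Fecundity is tied to competitive ability by a one-parameter superellipse,
$$r(C;\delta) = (1 - C^{p})^{1/p}, \qquad p = \frac{1-\delta}{\delta},$$
with $r \equiv 1$ at $\delta = 0$.  The family covers the qualitative
regimes usually discussed for life-history trade-offs: concave curves for
$\delta < 0.5$ (competitive ability is cheap), the linear trade-off
$r = 1 - C$ at $\delta = 0.5$, and convex curves for $\delta > 0.5$ where
even moderate competitive ability costs nearly all fecundity.  Every curve
is an involution (the family is symmetric in $C$ and $r$), $r$ is
continuous and non-increasing in both arguments, and $r(1;\delta > 0) = 0$.
The exact functional form behind a published trade-off is rarely
identifiable from its stated properties; the family is therefore isolated
behind `replication_probability()` so an alternative parameterisation can
be swapped in without touching the engine.

Note the superellipse is *severe* at high $\delta$: at $\delta = 0.85$ a
mid-range competitor ($C = 0.5$) has $r \approx 5\times10^{-6}$.  Since the
roster-mean of $C$ is pinned at 0.5 by reciprocity, high-$\delta$
communities replicate extremely slowly, which matters for what desk-scale
runs can show (see *Scales and limitations*).

### Design choices in the engine

Several micro-rules are underdetermined by the usual verbal description of
such models; the package fixes them as follows.

* **Out-of-range mutation noise** is clipped to $[0,1]$ and the
  complementary entry stored as the exact complement.  Redrawing instead of
  clipping would distort the effective noise distribution in an
  undocumented way.
* **Conspecific contests are real contests**: an offspring landing on a
  site held by its own strain fights at $I_{\alpha\alpha} = 0.5$; if it
  wins, the holder dies and the newborn takes the site *with a fresh
  lifespan*.  No exception for kin is part of the model.
* **Unestablished mutants found no strain**: a mutant offspring that loses
  its very first contest never enters the matrix or the lineage.  This
  keeps the genealogy restricted to strains that actually existed.
* **Replication failure consumes the trial** — there is no redraw.
* **Initial occupancy** defaults to 10% of sites, founder only.
* **RNG discipline**: one seeded stream with a fixed per-trial draw order
  (individual, replication coin, mutation coin, noise vector, site,
  contest coin, lifespan), which makes every trajectory bit-reproducible
  from its seed.
* **Neutral mode** keeps the full mutation machinery (traits drift) but
  decides all contests at probability 0.5 and fixes $r$ at `r_neutral`
  (default 0.5, matching the turnover of a linear-trade-off community whose
  strains sit near $C = 0.5$).  Global extinction ends a run with a flag,
  not an error — it is a legitimate model outcome at short lifespans.

## The mean-field counterpart

Averaging the trial rules over demographic noise for a *fixed* strain set
gives a competitive Lotka–Volterra system for occupancy fractions
$x_\alpha$ (total $X$):
$$\dot x_\alpha = \frac{r_\alpha x_\alpha}{X}(1-X)
  + \sum_{\beta\neq\alpha}\Big[\frac{r_\alpha x_\alpha}{X} x_\beta I_{\alpha\beta}
  - \frac{r_\beta x_\beta}{X} x_\alpha I_{\beta\alpha}\Big]
  - \frac{x_\alpha}{\lambda}.$$
The three parts mirror the trial events: colonisation of empty sites,
contest wins/losses, lifespan mortality.  `glv_integrate()` integrates it
with fixed-step RK4 (`dt = 0.1` generations; the dynamics are smooth and
bounded, and halving `dt` changes nothing at reported precision).

Two idealisations bound its validity, and both are visible in the test
suite rather than hidden:

* **The $x/\lambda$ mortality term treats the Poisson lifespan as a
  constant per-capita death rate.**  In the stochastic engine every
  newborn — including one that conquers an occupied site — draws a fresh
  lifespan, so at appreciable replication rates death clocks are reset at
  rate $\approx \bar r/2$ per capita and almost no individual ever reaches
  a lifespan $\lambda \gg 1/\bar r$.  A monomorphic population with $r = 1$
  therefore saturates at essentially full occupancy instead of the
  fixed-point prediction $x^\* = r\lambda/(1+r\lambda)$; the corresponding
  acceptance check fails by exactly that $1/(1+r\lambda)$ margin and is
  retained as an honest record of the model-structure discrepancy.  The
  same mechanism explains why lifespan matters mostly where $r$ is tiny
  (strong convex trade-offs): only there do lifespan clocks outrun contest
  resets.  For $\lambda = \infty$ the term vanishes and the correspondence
  is quantitative.
* **A generation is a *sequential sweep* of `ns` trials**, not an
  infinitesimal step.  During fast transients (per-capita growth of order
  one per generation) the within-generation updating deviates from the
  continuous flow by $O(10^{-2})$ in occupancy, independent of `ns`.  The
  mean-field comparison in the acceptance suite therefore samples
  trajectories in the smooth regime, where agreement across 20 replicate
  seeds is within stochastic error.

## The analysis stack

**Trait distances.**  The distance between strains $\alpha$ and $\beta$ is
the Euclidean distance between their rows *excluding the two coordinates
$\alpha$ and $\beta$*.  Raw rows always differ by
$|I_{\alpha\beta} - I_{\beta\alpha}|$ at their mutual coordinates even for
ecologically identical strains, which would put a floor under every
distance; dropping the self- and mutual entries leaves a symmetric measure
of behaviour towards third parties.  With only two strains there are no
third parties and the convention
$d = |I_{\alpha\beta} - I_{\beta\alpha}|/\sqrt2$ is used.

**Functional diversity** is the total weight of the minimum spanning tree
of the community in trait space (SMST): it grows as the population spreads
out and is unchanged by duplicating a strain.  **Species** are obtained by
cutting MST branches longer than a threshold $\theta$: the branch-length
distribution of a structured community is two-level (short within-cluster,
long between-cluster edges), and the automatic $\theta$ sits in the largest
relative gap of the sorted branch lengths, requiring at least a factor-3
gap before any cut is made (otherwise: one species).  *Functional groups*
are clusters at the coarser threshold $2\theta$.  Both thresholds are
overridable.  Species assignments are per-snapshot; across snapshots,
labels are chained by majority ancestry (each species inherits the label of
the previous-snapshot species that contains most of its members'
ancestors, by abundance; co-heirs split off as children).  This is the rule
that keeps Muller-plot colours stable; monophyly is a property to inspect,
not enforced.

**Classical multidimensional scaling** (`cmds_embed()`) is the standard
Torgerson double-centring eigendecomposition, reported with the fraction
of positive eigenvalue mass captured; embeddings are defined up to
isometry.

**The dominance network** keeps, per strain pair, only the superior
competitor's margin $W_{\alpha\beta} = \max(I_{\alpha\beta} -
I_{\beta\alpha}, 0)$ (exact ties: no edge).  Species-level edges average
$W$ over all ordered member pairs, zeros included, then reapply the
superior-competitor rule.  Intransitive cycles (rock–paper–scissors
motifs) are enumerated as simple directed cycles up to length 3 by
default (configurable to 5; enumeration cost grows steeply), a cycle's
*strength* being its weakest edge.  Because counts and strengths scale
with network size and weight magnitude, they are normalised by
"equivalent random networks": the node set and the multiset of pairwise
weights are kept, weights are reshuffled across pairs and each pair's
direction redrawn uniformly.  This destroys evolved structure while
preserving the weight scale, so a normalised mean cycle strength above 1
means cycles stronger than chance.

**Consensus diversity** averages ten min–max-normalised indices per
snapshot: strain and species richness, strain- and species-level Shannon
entropy, Pielou evenness, the Simpson index, SMST, mean pairwise trait
distance, mean distance to the trait centroid, and the functional-group
count.  Min–max normalisation is ensemble-relative, so the normalisation
ensemble is always explicit: all late-time snapshots of all runs of one
sweep.  Consensus values are comparable within a sweep and meaningless
across sweeps.  An index constant across the whole ensemble is mapped to
0.5; a run extinct before the averaging window contributes consensus 0.

**Speciation/extinction events** are read off the tracked species
trajectory: a speciation is the first recorded generation of a label that
persists at least `t_persist` (default: two snapshot intervals — transient
flickers are not events), an extinction the last recorded generation of a
persisting label that disappears before the end.  Inter-event times are
tested against a constant-rate Poisson process: exponential MLE fit, a
Kolmogorov–Smirnov distance, and a parametric bootstrap p-value (the
bootstrap refits the rate for every synthetic sample, which is what makes
the test valid with an estimated rate).  Its type-I error is verified to
be at the nominal level on synthetic Poisson series in the acceptance
suite.  Event-time resolution is the snapshot interval; `record_every` is
a parameter precisely because event statistics inherit it.

## Scales, study conditions, and limitations

The bundled tests and the acceptance script run at desk scale:
`ns = 1000` sites, $5\times10^4$ generations, $\mu = 10^{-3}$, $m = 0.02$,
$\lambda = \infty$, five seeds per trade-off cell
($\delta \in \{0.1, 0.5, 0.85\}$) plus a neutral baseline; mean-field
checks use `ns = 10^4`.  At these sizes a sweep takes a few minutes.

What desk scale does and does not show:

* The **humpback of diversity over trade-off** is reproduced: median
  consensus diversity peaks at the linear trade-off and collapses for
  strong convex trade-offs.
* **Emergent dominance structure is a large-system effect.**  At
  `ns = 1000` the evolving communities hold only a handful of strains;
  genetic drift erodes nascent trait clusters before inter-cluster
  dominance margins can grow, and neither the mean dominance weight nor
  the normalised cycle strength at $\delta = 0.5$ rises reliably above
  the neutral baseline.  The corresponding acceptance checks fail at this
  scale and are retained as such; the same statistics computed by the
  package on larger/longer runs (the package imposes no size limit) are
  how the structured phase is actually studied.
* **Strong convex trade-offs are slow, not neutral, at desk time
  scales.**  Because $r(C \approx 0.5; \delta = 0.85) \sim 10^{-5}$, a
  $5\times10^4$-generation run performs only a handful of effective
  turnover events: the community is nearly frozen at two or three strains
  and its consensus diversity sits *below* the neutral baseline, instead
  of matching it as it would after enough effective generations.  The
  acceptance comparison of the $\delta = 0.85$ cell against the neutral
  cell fails for this reason and is kept as an honest record of the
  time-scale limitation.

The synthetic-data generators used by the tests
(`random_reciprocal_matrix()`, `random_tournament()`,
`planted_cluster_traits()`, `planted_cycle_network()`) emulate valid
reciprocal communities, tournaments with one direction per pair, planted
trait clusters of known spread/separation, and planted cycles of known
strength.  They are fixtures with exact ground truth — they do not emulate
demographic correlations, abundance structure, or the
relatedness–similarity coupling of evolved communities, so tests passing
on them validate the *statistics*, not the realism of any particular
evolved trajectory.

## Reading a run

```{r example, eval = FALSE}
cfg <- sim_config(ns = 1000, delta = 0.5, lambda = Inf, mu = 1e-3,
                  m = 0.02, generations = 50000, seed = 42,
                  record_every = 2500)
sim <- run_simulation(cfg)
summary(sim)

sn <- sim$snapshots[[length(sim$snapshots)]]
diversity_report(sn)             # ten indices for the final community
network_stats(sn$matrix)         # <W>, cycle count, normalised strength
mt <- muller_table(sim)          # species-resolved trajectory
detect_events(mt$population)     # speciation / extinction times
cat(to_newick(sim$lineage, t_end = 50000, live_only = TRUE))
```

A phase-diagram sweep is a single call
(`run_sweep(deltas = ..., lambdas = ..., seeds = ...)`) and writes to TSV
via `write_phase_diagram()`; single runs export their standard delimited
outputs with `write_run()`.
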