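---
title: "Digital time-travelling invasions: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital time-travelling invasions: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invasim)
```

## The question

When long-dormant pathogens re-emerge — from thawing permafrost, melting
glaciers, or laboratory archives — they meet communities with which they
share no recent coevolutionary history. `invasim` studies this situation *in
silico*: it evolves digital host–pathogen communities, then replays a
community's history from a shared random seed and injects a pathogen sampled
from that community's own past into its future, so that the injected
genotype is a genuine "time traveller" whose lineage has already gone
extinct in the recipient. Because the control and invaded runs are
bit-identical up to the moment of injection, every post-injection difference
is causally attributable to the invader.

## The world model

The simulator is a deliberately reduced stand-in for instruction-level
digital-evolution systems (Avida and its host–parasite extensions). It keeps
the ecological skeleton those systems give to invasion biology — task-based
merit, limited resources with by-product cross-feeding, task-overlap
infection, CPU-cycle parasitism — while replacing the virtual CPU with a
9-bit task genome.

**Organisms and tasks.** A genotype is a subset of nine logic tasks (NOT,
NAND, AND, ORN, OR, ANDN, NOR, XOR, EQU) with complexity weights 1, 1, 2, 2,
3, 3, 4, 4, 5, packed as a 9-bit mask. A "species" is a distinct genotype:
every mutation event creates a new node in the genotype phylogeny, with the
number of flipped bits recorded as the branch length.

**Grid and occupancy.** Hosts live on a toroidal grid (one host per cell;
2,500–15,000 cells at full scale), each host carrying at most one pathogen.
The torus with a Moore (8-cell) neighbourhood avoids edge artefacts;
offspring overwrite a random neighbour (and its pathogen), which is the only
source of host death — as in Avida, death is by replacement.

**Resources and merit.** Nine global resource pools are each consumed by
exactly one task (a per-configuration random bijection). Per update, each
pool receives a uniform random inflow within a per-configuration bound and
loses a uniform random fraction; a random subset of 3–9 resources has
non-zero inflow, spanning scarce to rich environments. Performing task $t$
consumes up to one unit per performer per update (split evenly when the pool
is short) and excretes a by-product into a random pool at a ratio drawn once
per configuration in $[0, 0.5]$ — a random biochemical network unique to
each world. Merit is multiplicative in task complexity,
$2^{\sum_t c_t u_t}$, where $u_t \in [0,1]$ is the realised per-capita
consumption: crowded resources confer a vanishing advantage, which is the
frequency-dependent mechanism that sustains coexistence. A global CPU budget
of 30 cycles per host per update is divided merit-proportionally.

**Infection and parasitism.** A pathogen can infect a host only if it
performs at least one of the host's tasks. Infected hosts yield a fixed
fraction (default 0.5) of their allocated cycles to their pathogen. Pathogen
offspring are emitted as single propagules to uniformly random cells and
survive only if they land on a susceptible, uninfected host; pathogens also
die with their host or at a replication-age cap (default 100 updates).
Free-living and pathogenic lifestyles never interconvert.

**Replication and mutation.** A host replicates when its accumulated CPU
reaches a cost $150(1 + 0.35\sum_t c_t)$: tasks cost genome space, so a task
is only favoured while its resource reward outweighs the slower
replication. Pathogens replicate at a flat cost of 100 stolen cycles. Each
offspring flips each task bit independently (defaults: $2\times10^{-3}$ per
bit for hosts, $5\times10^{-3}$ for pathogens — pathogens evolve faster,
consistent with their shorter generations in host–parasite digital
evolution).

**Ancestors.** Each run starts from one free-living ancestor performing NOT;
a small ancestral pathogen population (also NOT) is injected into 5% of
cells at 5% of the run. The task-overlap rule requires the ancestors to
share a task for the epidemic to start, so neither ancestor is task-free.

Parameters without a stated precedent (theft fraction, propagule number,
age cap, replication costs, the task-cost factor, inflow bounds) were fixed
once, on ecological grounds, to give persistent epidemics with intermediate
prevalence (~0.5–0.8), tens of coexisting genotypes of each kind, growing
host task complexity, and pathogen extinction in a minority of runs — the
regime the paired-invasion design needs. They are ordinary configuration
fields, not claims about any reference system.

## The experimental protocol

At scale 1, a run lasts 250,000 updates with a census every 100 updates. A
paired experiment:

1. runs the **control** to completion from seed $s$;
2. draws the source time $t_{sample}$ uniformly from [20%, 60%] of the run
   and the manipulation time $t_{man}$ from (60%, 80%], snapped to recorded
   snapshots;
3. samples one pathogen genotype from the $t_{sample}$ census with
   probability proportional to abundance, requiring its lineage (itself plus
   all descendants) to be extinct at $t_{man}$ — at reduced scale this is
   enforced by resampling (up to 30 tries; failures are flagged and
   excluded);
4. replays the **treated** run from the same seed $s$ — bit-identical by
   construction — and at $t_{man}$ injects the stored genotype into 5% of
   cells (uninfected, susceptible resident hosts become infected; all other
   propagules die). Injection draws come from a dedicated RNG stream so the
   injection itself is the only difference between the futures.

Two baselines isolate confounders: **control–control** pairs replace the
injection with a switch to a fresh RNG stream (the natural between-future
variation; the control run is designated the reference *a priori*), and
**contemporary-enrichment** pairs inject an abundance-weighted *extant*
pathogen (the density shock of injection without the temporal displacement).
Pairs whose pathogens die out before $t_{man}$ are excluded from analysis,
as in the full-scale protocol.

## Outcome analytics

**Persistence.** The invader's lineage persistence is the number of
post-manipulation updates its lineage remains extant, computed on the
recorded cadence with a last-seen convention (alive through the last
snapshot seen alive) and capped at 20% of the run (50,000 updates at full
scale). The identical rule applies to every native pathogen lineage, so the
per-pair comparison — the fraction of natives less persistent than the
invader, restricted to natives at least as abundant as the invader at
$t_{man}$ — is fair by construction. Campaign-wide, the number of invaders
reaching the cap is tested against the native baseline rate with an exact
upper-tail binomial probability computed in log space. The baseline defaults
to the campaign-wide fraction of native lineages reaching the cap; the
alternative reading (the invader share of pathogens at manipulation time)
can be supplied as `q` directly, and neither is asserted to reproduce any
specific published p-value, whose exact inputs are underdetermined.

**Diversity change.** Free-living diversity series (richness, abundance,
Shannon $H' = -\sum_i p_i \ln p_i$ in natural-log units, Pielou evenness
$H'/\ln S$, Faith's PD) are compared between the runs of a pair by
trapezoidal area under the curve over a 1%-of-run window after $t_{man}$
(2,500 updates at 100-update resolution at full scale), as the relative
percent change $100\,(A_{con} - A_{inv})/A_{con}$ — positive is a loss in
the invaded community. Richness is the headline metric; a window-sensitivity
grid ({500, 1000, 2500, 5000} updates, scaled) probes robustness. Branch
lengths for Faith's PD and for invader–native phylogenetic distance are
accumulated task substitutions by default (update-time lengths are an
option); substitution counts are the natural metric of a genotype-level
phylogeny, but neither unit is asserted to match any external convention.

**Feature screen and prediction.** Twenty-one features of the environment,
the recipient community, and the invader's first existence are extracted per
pair and screened against the outcomes (invader persistence, signed and
absolute change) with Spearman's rank correlation (no multiple-testing
correction is applied to the screen — it is a screen, not a test family).
"Net available resources" is the expected total inflow per update (the
inflow bounds are drawn per configuration; their expectation summarises
them); "density" is individuals per grid cell over the whole world. Pairs
with substantial losses versus substantial gains (|change| > 5%) are
contrasted with a two-sided rank-sum test, exact by enumeration for pooled
sizes up to 12 without ties. Random-forest regressions (1,000 trees) on the
17-feature modelling subset (the environment features and post-invasion
generalism are dropped; the change models add invader persistence as a
predictor) report out-of-bag explained variance and permutation importance
(%IncMSE); the `randomForest` package is used directly rather than
reimplemented.

**Generation equivalence.** To place update counts on a biological
timescale, the package carries a Fermi-style calibration: a full-scale run
accumulates roughly 400 substitutions along the focal pathogen lineage;
treating one fixed substitution as one bacterial substitution at
$10^{-4}$–$2\times10^{-4}$ per generation maps 250,000 updates to 2–4
million bacterial generations, and the 50,000–150,000-update sampling window
to 400,000–2,400,000 generations. `lineage_substitutions()` recomputes the
substitution count from any phylogeny; the conversion itself is arithmetic,
exposed with overridable constants.

## Scale, determinism, and numerical choices

All analyses in the test-suite and acceptance script run at scale 0.04
(worlds of 100–600 cells, 10,000 updates, windows scaled in proportion: a
2,000-update persistence cap, a 100-update diversity window at 4-update
resolution) with campaigns of 30 configurations × 2 replicates; these sizes
were chosen so the entire protocol runs in minutes on one core while keeping
tens of genotypes per community. The headline statistics of the full-scale
system (e.g. the published percentages of highly persistent invaders or the
extreme loss/gain values) are emergent properties of instruction-level
genomes at 25× these sizes and are **not** reproduction targets for the
reduced model; what the package asserts instead are the properties that do
transfer: replay identity, invariant soundness, oracle-exact metrics,
abundance-weighted sampling, exclusion filtering, and the self-contained
arithmetic.

Determinism is strict: one global RNG stream seeded per run drives the
dynamics; scheduling/sampling, injection, and the control–control reseed use
dedicated derived streams, so any pair or campaign is bit-reproducible from
its master seed. Ties (overwrite order, propagule precedence) are broken by
the RNG, never by array order. Resource subtraction is clamped at zero
against floating-point round-off. Snapshot identity is checked by content
hashes of census plus infection edges.

Degenerate inputs are handled explicitly: empty sampling windows, pairs with
extinct pathogens, invaders that establish zero infections (they receive a
persistence-0 row rather than silently vanishing), communities with no
qualifying natives (the per-pair comparison is undefined and the pair is
dropped from that statistic), and constant features in the Spearman screen
(reported as `NA`).

## What the generator does and does not emulate

The synthetic worlds reproduce the statistical structure the analyses
assume: genotype-level censuses and infection networks on a shared clock,
phylogenies with substitution branch lengths, paired futures from shared
seeds, and heterogeneous environments. They do not emulate instruction-level
genomes (so task gain/loss is a single-bit event, not a multi-instruction
pathway), plasticity, recombination, multi-infection, or vertical
transmission; and at 1/25 scale, drift is stronger and lineage turnover
faster than at full scale. Conclusions from the reduced model about effect
*sizes* in the full-scale system are therefore out of scope; the package's
tests demonstrate correctness of the machinery, not equivalence of the
ecosystems.

## Session problem sizes

```{r sizes, eval = FALSE}
cfg <- build_config(1, scale = 0.04)   # ~100-600 cells, 10,000 updates
pair <- run_pair(cfg, "time_travel", pair_seed = 1)
camp <- run_campaign(30, 2, "time_travel", master_seed = 1, scale = 0.04)
analysis <- analyze_campaign(camp)
```
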