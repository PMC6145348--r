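---
title: "Modelling lake redox cycling with gene-constrained calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lake redox cycling with gene-constrained calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lakeredox` models the seasonal biogeochemistry of a small, seasonally
stratified, anoxic-bottomed lake and the microbial data types used to
constrain such a model: depth profiles of redox-sensitive chemistry,
functional-gene relative abundances from shotgun metagenomics, and matched
16S OTU / metagenome-assembled-genome (MAG) community tables. This vignette
is the package's account of the science: the model, its assumptions, the
tunable parameters, and the design decisions taken where the problem was
genuinely open.

## The reaction network

The water column is described by 14 microbially mediated processes: primary
carbon oxidation down the electron-acceptor ladder (O2, NO3-, Fe(III),
SO4^2-, and methanogenesis), re-oxidation of the reduced products (NH4+,
CH4, HS-, Fe2+) with oxygen, anaerobic methane oxidation with sulfate,
autotrophic denitrification by iron oxidation, two nitrate-coupled
oxidations motivated by MAG gene content --

    5 HS- + 8 NO3- + 3 H+  ->  5 SO4^2- + 4 N2 +  4 H2O
    5 CH4 + 8 NO3- + 8 H+  ->  5 CO2    + 4 N2 + 14 H2O

-- and a first-order precipitation sink for reduced sulfur standing in for
iron monosulfide, pyrite and organic-sulfur burial. Organic matter is the
CH2O proxy; oxidised iron is carried as Fe3+. Every reaction balances
exactly in each element and in charge; `check_balance()` verifies this with
exact arithmetic and `balance_minimal()` solves the conservation system for
the smallest positive integer coefficients (it reproduces both
stoichiometries above from the species compositions alone). The balancing
uses a small exact rational linear-algebra kernel rather than floating
point, so balance tests are identities, not tolerance checks.

Two bookkeeping choices matter. H+ and H2O appear in stoichiometries so the
balances close, but pH and the water budget are not modelled: both species
are flagged `balance_only` and excluded from kinetics, transport and
nonnegativity. The sulfur precipitate `Sppt` is an immobile species with
the composition of HS-, so precipitation moves sulfur to a tracked inert
pool and element conservation remains exact even with the sink active.

Kinetics are dual-Monod with optional oxygen inhibition on the anaerobic
processes,

$$ r = k\,\frac{[D]}{K_D + [D]}\,\frac{[A]}{K_A + [A]}\,
       \frac{K_I}{K_I + [\mathrm{O_2}]}, $$

with `k` in uM/year and half-saturations in uM; the precipitation sink is
first-order (1/year). The process definitions do not by themselves fix a
kinetic form; dual-Monod with oxygen inhibition is the standard choice in
lake reactive-transport models and is adopted here as a declared
assumption. Default maximum rates (1e2-6e3 uM/year) and
half-saturations (2-100 uM) are order-of-magnitude values typical of
seasonally anoxic lake models; they are the package's fixed reference
configuration, not fitted quantities.

## The transport model

`integrate_lake()` solves the method-of-lines system

$$ \partial_t C_s = \partial_z\!\left(D(z)\,\partial_z C_s\right)
   + \sum_r \nu_{s,r} R_r(C) $$

on a uniform finite-volume grid, by default 23 cells of 1 m (the lake is
about 23 m deep and was sampled at 1-2 m intervals). Depth increases
downward with cell centres at (i-1/2) dz. Diffusivity is a static two-layer
profile -- 10 m^2/day in the epilimnion, 0.02 m^2/day in the hypolimnion,
logistic transition at the 8 m thermocline -- chosen so the surface layer is
effectively mixed while the hypolimnetic mixing time far exceeds the
season. The seasonal deepening of the thermocline is not parameterised: a
static D(z) is the deliberate default; no quantitative seasonal forcing is
assumed where none is measured.

Boundary conditions: O2 is held at surface saturation (300 uM) and CH4,
HS- and NH4+ at zero at the surface (an outgassing/rapid-oxidation proxy);
CH4, NH4+, Fe2+, HS- and organic matter enter at the bottom as constant
sediment influxes (4-25 uM m/day). This reproduces the observed structure
-- reduced species accumulating at depth under an oxic cap -- without a
sediment diagenesis model. All other species have zero-flux boundaries.

Integration uses `deSolve::lsoda` with a banded Jacobian (state ordered
cell-major so the bandwidth is the species count) and a compiled
derivative function, relative and absolute tolerance 1e-6 by default. Kinetics are evaluated on concentrations clipped
at zero inside the RHS; saved outputs are clipped at zero with the clipped
mass recorded in the run ledger (it stays at the solver-noise scale, orders
of magnitude below field totals). The ledger also tracks S, N, Fe and C
column totals; with closed boundaries these are conserved to solver
precision for any balanced network, which the test suite asserts over 50
random sub-networks. Internally time is days and depth metres; rates are
reported in uM/year.

## Genes as process proxies

Functional-gene observations are normalised in two steps: copies per
million within each sample, then L1 within each gene across samples
(`normalize_gene_profile()`). The modelled counterpart of a gene profile
rests on the proportionality assumption -- cells grow in proportion to the
energy flux of the processes their genes mediate, and dispersion
distributes them smoothly -- so the proxy is the sum of the mapped process
rates, interpolated to the sampling depths (linear in depth, nearest saved
time) and L1-normalised (`modeled_gene_proxy()`). The default map:

| gene set | modelled processes |
|---|---|
| pmoABC | nitrification, CH4 oxidation with O2, CH4 oxidation with SO4 |
| dsrAB | sulfate reduction, sulfide oxidation (O2 and NO3-) |
| nosDZ | heterotrophic denitrification, iron and sulfide oxidation with NO3- |
| mxaCGKL | CH4 oxidation with O2 and with SO4 |
| hoa | nitrification |
| ironred | heterotrophic iron reduction |

pmoABC covers ammonia co-oxidation by the promiscuous monooxygenase; dsrAB
is bidirectional (reductive and oxidative sulfur cycling); nosDZ covers
heterotrophic plus autotrophic denitrification, where autotrophic
denitrification here means the iron- and sulfide-oxidising routes (the
known methane-oxidising denitrifiers typically lack nosZ, so
nitrate-coupled methane oxidation is deliberately not mapped to nosDZ).

The fit metric is the unweighted mean absolute error across observables
(`build_objective()`): one MAE per chemistry (species, time) profile and
one per gene set. Chemistry profiles are L1-normalised per profile before
comparison. This is a declared choice: gene observables are only defined on
a relative scale, a shared [0, 1] scale makes the unweighted average
meaningful, and fit values around 0.2 are only plausible on normalised
profiles. A `weights` argument exposes the weighting should chemistry and
genes need unequal influence. Profiles that are identically zero are
compared as-is with a warning rather than renormalised.

## The calibration algorithm

`calibrate()` implements a stochastic, sequential, bounded search. Each
iteration draws `m` parameter vectors from truncated Gaussians inside the
literature bounds (rejection resampling, so no probability atoms at the
bounds), evaluates the objective, and regresses the fit metric on each
unfixed parameter separately; the regression F test (F = (m-2) R^2 / (1 -
R^2) on (1, m-2) degrees of freedom) ranks sensitivity. Outside the
burn-in, the lowest-p parameter is fixed at its value in the best sample of
that iteration; exact p ties fall to the earlier parameter in spec order.
Remaining centres are re-set by the regression rule

$$ c' = \mathrm{clip}\!\left(c - \lambda\,\sigma^2\,
        \frac{\hat\beta}{\mathrm{sd}(\mathrm{objective})},\;
        [\mathrm{lower}, \mathrm{upper}]\right), $$

a standardised downhill step (lambda = 1 by default), and the new sigma is
the distance just moved, floored at 2% of the bound width so sampling never
degenerates. The best configuration found so far is re-evaluated as the
last of the m samples (elitism): the sample set is otherwise pure Gaussian
draws, and without the incumbent the per-iteration best objective loses
ground in a quarter or more of seeded runs even on smooth objectives, while
with it the best is nonincreasing by construction and the sequential fixing
inherits coordinates from a steadily improving incumbent. The source description says only that regressions "reset the
centers" and the centre displacement "defines the shape" of the next
Gaussian; the rule above is this package's concrete reading, and the
burn-in also re-centres (it exists to initialise the centres). "Best-
fitting value" is read as the parameter's value in the lowest-objective
sample of the current iteration.

Once every parameter is fixed, a bounded quasi-Newton polish
(`stats::optim`, L-BFGS-B) refines the converged point. Three numerical
choices matter here, all driven by the fact that the objective is computed
by an ODE solver over shape-normalised profiles. First, the finite-
difference step defaults to 1e-3 of each bound width: much smaller steps
(1e-6, the conventional choice) probe solver error rather than the
objective and leave the gradient pure noise, measurably stalling the
descent. Second, the descent can run in log coordinates
(`transform = "log"`), the natural geometry for rate constants, which act
multiplicatively; on the recovery experiments the linear-coordinate descent
stalls partway down the flat valley of the MAE surface while the
log-coordinate descent reaches the planted truth. Third, two passes are run
back to back, restarting L-BFGS-B at its own output, which recovers
progress after line-search stalls on the piecewise-linear surface. The
polish never returns a point worse than its start.

Everything is driven by one integer seed; per-iteration seeds are derived
from it, and identical seeds give bitwise-identical iteration records.

## Matching OTUs to MAGs

A MAG's raw abundance in sample j is its length-weighted mean contig
coverage, A_j = sum(l_i c_ij) / sum(l_i), divided by the library read
count. OTU and MAG tables restricted to the shared samples are normalised
with the dual-axis L1 scheme -- within samples first, then within features
-- and candidate pairs are scored by

$$ m = \lVert \mathrm{otu} - \mathrm{mag} \rVert_2 - f, $$

where f is the fraction of matching taxonomy levels, each of the six ranks
(kingdom-genus) compared independently, with the number of assigned MAG
ranks as denominator. A perfect pair (identical rows, full taxonomy match)
scores exactly -1, the metric's true lower bound; the nominal upper end on
dual-L1 rows is sqrt(2) - 0, so describing the metric's range as [-1, 1]
is an empirical observation about real tables, not a clamp. Ranks with RDP
confidence below 50% or named *Incertae Sedis* are treated as unassigned
(`filter_taxonomy()`), levels independently.

The acceptance tolerance is trained on known-correct control pairs as the
smallest threshold admitting all of them (`train_tolerance()`), separately
per dataset, and a pair is accepted only if it is within tolerance in
*both* the amplicon and the metagenomic dataset. Accepted pairs are
assigned one-to-one, greedily by ascending amplicon metric with
lexicographic tie-breaks; a `many_to_one` flag relaxes the one-to-one rule.
Max-over-controls training only generalises when the controls span the
hardest correct cases -- a tolerance trained solely on easy (full-taxonomy)
controls will reject harder true pairs. The synthetic community generator
therefore places its worst taxonomy matches inside the control set, which
mirrors how control bins with imperfect classifications anchor the
threshold in practice. Candidate pre-filters (such as keeping only the top
OTUs by total abundance) are the caller's responsibility and should be
applied before normalisation.

Gene-content clustering of features (`cluster_gene_content()`) uses the
Spearman rank-correlation distance 1 - rho with complete linkage; constant
profiles are rejected by name since their ranks are undefined.

## Knockouts and sweeps

`knockout()` sets the rate constants of named processes to zero, leaving
every other parameter untouched; `knockout_compare()` runs the scenario
with and without the processes and reports, per species, the concentration
summed over all depths and saved times, and the percent change against the
baseline total (undefined, not zero, when the baseline is zero).
`parameter_sweep()` repeats the comparison over n parameter draws, uniform
within the bounds by default (Gaussian-from-centre available), purely
sampling -- no per-draw re-calibration -- and aggregates mean/min/max per
species. Removing the two nitrate-coupled oxidations removes nitrate
sinks, so the oxidised-nitrogen total cannot drop; the test suite asserts
this directionally on the calibrated synthetic scenario.

## The synthetic data generators

All generators are pure functions of (configuration, seed).

`make_scenario()` draws the free rate constants log-uniformly inside
factor-of-three bounds around the defaults (standing in for
literature-derived limits), records the truth, and simulates a 140-day
season saved weekly. The default free set is the four primary
carbon-oxidation pathways -- sulfate reduction, iron reduction,
methanogenesis and heterotrophic denitrification. They compete for the same
organic-matter pool through distinct electron acceptors and marker genes
(SO4/dsrAB, Fe2/ironred, NO3/nosDZ, CH4-cycling genes), so each constant
remains a major, distinguishable flux anywhere inside its bounds. Freeing
secondary oxidation constants instead makes the experiment ill-posed
whenever their truth lands near the lower bound, where the process is too
weak to mark any observable -- a genuine identifiability limit of
shape-normalised objectives, not an algorithm failure.
`make_observations()` adds
mean-preserving multiplicative lognormal noise to profiles interpolated at
the sampling depths (1-21 m every 2 m) and dates. `make_gene_tables()`
perturbs the noise-free proxies the same way and renormalises, so at zero
noise the gene tables close the loop with `modeled_gene_proxy()` exactly.

`make_community()` plants latent populations as depth-Gaussian bumps over
11 shared samples and emits them through two independent noise channels:
multinomial read counts for the amplicon and metagenomic OTU tables
(50,000 and 10,000 reads per sample), and lognormal per-contig coverage
noise for the MAG contigs (3-10 contigs each). Partner-less extra OTUs are
added at half amplitude. Taxonomies come from a nested toy hierarchy
(10 phyla widening to ~29,000 genus-level paths); planted OTUs match their
MAG's path down to 6, 5 or 4 ranks, the 4-rank (hardest) matches confined
to the controls, and extras are kept at most class-level-similar to any
planted MAG so that "no partner" remains well defined.

What the generators deliberately do not emulate: read-level sequencing
(FASTQ, chimeras, contamination), compositional coupling between community
members beyond closure, copy-number variation of marker genes, binning
errors (contigs never land in the wrong MAG), and taxonomy-assignment
noise beyond truncation depth. Passing tests therefore demonstrate that
the algorithms recover planted structure under the stated noise channels,
not that they are robust to every artefact of real libraries.

## Numerical choices and problem sizes

Solver tolerances default to 1e-6 (relative and absolute, uM); balance
checking is exact rational arithmetic; interpolation is linear in depth
with constant extrapolation and nearest-neighbour in time. The test suite
and the analysis scripts run scaled-down experiment sizes chosen as the
package's own testing configuration: the calibration recovery experiment
uses the first 60 days of the season with observations at days 20/40/60,
solver tolerance 1e-7 (the descent needs objective differences well above
solver error), m = 60 samples per iteration (the algorithm is normally run
with 100-1000), 4 free constants, and the log-coordinate polish; the
knockout sweep uses tens of draws; the matching experiment uses the full
default community.

## Known limitations

* No pH/alkalinity, temperature dependence, isotopes, or explicit biomass
  pools; rates respond to chemistry only.
* The static two-layer diffusivity ignores seasonal thermocline deepening;
  simulated late-season profiles are smoother than observed ones.
* Identifiability of rate constants from shape-normalised profiles is
  limited: constants whose processes share an electron acceptor partially
  compensate, and only well-separated free sets are recovered tightly.
* The combined OTU-MAG metric weighs one taxonomy level as exactly 1/6 of
  a Euclidean distance unit; with very short sample vectors the abundance
  term carries little information and taxonomy dominates.
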