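---
title: "Models and methods behind crossfeedr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crossfeedr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossfeedr)
```

crossfeedr implements the computational core of a serial-transfer evolution
experiment with a two-species commensal community: a cross-feeder consumes a
primary carbon source (benzyl alcohol) and leaks a by-product (benzoate)
that a second, focal species depends on. The package covers four connected
pieces: batch Monod growth and community simulation, resource-use trait
estimation from plate-reader curves, evolutionary statistics on mutation
tables and competition assays, and a bimodality test for trait
distributions. This vignette records the models, the tunable parameters,
the numerical choices, and the places where the design was genuinely open.

## Batch growth and the cross-feeding chain

Within one growth cycle every genotype grows by Monod kinetics on its
resource pool,

$$\frac{dP}{dt} = Y\,\frac{V R}{K + R}\,P, \qquad
  \frac{dR}{dt} = -\frac{V R}{K + R}\,P,$$

with density $P$ in OD units, resource $R$ in mM, yield $Y$ (OD/mM),
maximum uptake rate $V$ (mM/OD/h) and half-saturation constant $K$ (mM).
The maximum growth rate is tied to the other traits by
$\mu_{\max} = Y V$; `genotype()` enforces this so that supplying any two of
$(\mu_{\max}, Y, V)$ determines the third. Biomass and resource obey the
conservation identity $P(t) - P_0 = Y\,(R_0 - R(t))$, which the test suite
checks against the integrator at every output time.

A producer genotype (the cross-feeder) adds a leak term: a fraction
$\ell \in [0,1]$ of everything it consumes appears in its product pool,
`dB/dt += l * uptake`. The producer's own kinetic constants and $\ell$ are
not measured quantities; they are configuration with defaults chosen to be
biologically plausible ($\ell = 1$, a pure commensal pass-through, and
cross-feeder kinetics of the same order as the consumer's). Only the fact
that the consumer's resource supply is biogenic matters for the qualitative
behaviour.

Serial transfers follow the laboratory protocol: grow for 24 h, record
end-of-cycle densities, dilute 1:100 (100 µL into 9.9 mL) and replenish
fresh medium. Each cycle therefore contributes $\log_2 100 \approx 6.6$
generations of regrowth. Within-cycle dynamics are deterministic
(populations of $10^5$–$10^7$ CFU/mL leave no room for demographic noise at
the resolution of daily plate counts); stochasticity enters through
multiplicative lognormal plating noise on the recorded counts and,
optionally, Poisson sampling of transferred cells. Densities are reported
in CFU/mL through a fixed configurable conversion (1 OD = 5×10⁸ CFU/mL by
default); recorded values below the detection limit (10² CFU/mL) are
flagged censored rather than zeroed, and the underlying ODE state is never
truncated.

Integration uses `deSolve::lsoda` with relative tolerance $10^{-8}$ and
absolute tolerance $10^{-10}$; tiny negative excursions within solver
tolerance are clipped to zero on output.

## Trait estimation from OD curves

`estimate_traits()` implements a multistep procedure on blank-corrected,
10-minute-interval, 24-h curves:

1. **Yield.** $Y = (OD_{\max} - OD_{\min})/R_0$. $OD_{\min}$ is the mean
   of the first three readings. $OD_{\max}$ is the plateau of the isotonic
   (monotone) regression of the median-filtered curve rather than the raw
   maximum: a raw maximum over ~145 noisy readings is biased upward by
   roughly two noise standard deviations, which propagates into every later
   step. A rise smaller than the instrument floor ($10^{-4}$ OD) is
   reported as no growth with $Y = 0$.
2. **Growth rates.** $\mu = \Delta \ln OD / \Delta t$ by centred sliding
   5-point (50-min) linear regression of log OD, after a width-3 median
   filter; readings at or below the $10^{-4}$ OD floor are floored before
   the log.
3. **Resource reconstruction.** Inverting the yield relation,
   $R(t) = R_0 - (OD(t) - OD_{\min})/Y$, on the isotonic OD curve, clipped
   at zero, so $R$ is monotone non-increasing by construction.
4. **Uptake.** $q = \mu / Y$ (mM/OD/h), paired with the resource averaged
   over the same window that produced the slope. Pairing a windowed slope
   with a point value of $R$ misaligns the two during the fast depletion
   phase; window-averaging both keeps them consistent.
5. **Monod fit.** Nonlinear least squares of $q = V R/(K+R)$
   (`minpack.lm::nlsLM`) with multi-start initialisation
   ($V_0 = \max q$, $K_0 = \mathrm{median}(R) \times \{0.2, 1, 5\}$),
   bounds $V \in (0, 10 V_0]$, $K \in [10^{-4}, 10 \max R]$. Only
   growth-phase windows enter the fit: windows past 95% of the OD rise
   carry no kinetic signal, only slope noise, and points with
   $R < 0.01 R_0$ are excluded because near depletion the reconstructed
   $R$ inherits the yield's uncertainty.

When technical replicates share a time grid, their log-OD curves are
averaged before any differentiation, so the noise entering the slope
estimates falls by the square root of the replicate count; otherwise the
$(R, q)$ clouds are pooled.

Finally, the multistep estimates seed a joint fit of the *integrated*
batch model to all replicate curves on the log-OD scale (multiplicative
measurement error), with $(Y, V, K, P_0)$ free. This is the step that
sharpens $V$ and especially $K$: the half-saturation constant is only
expressed during the short depletion phase — with $K/R_0 = 0.1$ and
typical rates, roughly a 20-minute window covering two readings per curve
— and differentiation throws away most of that information. The refinement
can be disabled (`refine = FALSE`) to obtain the pure multistep estimates.

Two flavours of the maximum growth rate are reported. `mu_max` is the
Monod-implied maximum $\hat Y \hat V$, the quantity the linked-trait
identity refers to. `mu_max_obs` is the largest windowed slope whose mean
OD lies in the exponential-phase band
$[OD_{\min} + 0.1\,\Delta OD,\; OD_{\min} + 0.7\,\Delta OD]$; it is capped
below $YV$ by resource draw-down (at most $Y V R_0/(K+R_0)$, a bound the
tests check with 10% slack), and is the honest "slope of the log curve"
summary.

**What accuracy to expect.** The test suite and the acceptance script
measure recovery on simulated curves: noiseless round trips recover all
four traits essentially exactly, and at 5% multiplicative OD noise with
three technical replicates the median errors are a fraction of a percent
for $Y$, a few percent for $V$ and $\mu_{\max}$, and 15–20% for $K$. The
$K$ figure is not an implementation artefact: fitting the exact generating
model by maximum likelihood on the same data gives the same median error,
i.e. the 10-minute, 24-h, three-replicate design simply contains roughly
that much information about $K$ at $K/R_0 = 0.1$. Experiments that need a
sharper $K$ need either lower starting resource (so the transition phase
lasts longer) or faster sampling through the depletion phase.

## Trait comparison and bimodality

`compare_traits()` is a Welch two-sample two-tailed $t$ test plus the
fold-change of means ("two-tailed t test" alone does not fix the variance
assumption; the unequal-variance form is the safe default). Degenerate
zero-variance comparisons return $p = 1$ when the means agree exactly.

`test_multimodality()` computes the Hartigan dip statistic — the sup-norm
distance between the empirical CDF and the closest unimodal CDF — with a
bootstrap null: `n_boot` uniform samples of the same size, $p$ the
fraction of null dips at least as large as the observed one. The uniform
is the classical least-favourable unimodal null for the dip.

No dip implementation is bundled with the package's dependencies, so the
statistic is implemented from first principles. A unimodal CDF is convex
left of its mode and concave right of it, with an atom allowed at the
mode. Being within $\varepsilon$ of the empirical CDF constrains the
candidate at every sample value to a band
$[k/n - \varepsilon,\ (k-1)/n + \varepsilon]$, and feasibility of a convex
function through bands reduces to a greatest-convex-minorant chord
condition. Minimising over mode positions gives an exact algorithm built
from incremental hulls plus a "join" feasibility check that the two sides
can be connected monotonically through the mode (forced slopes between
band corners propagate toward the mode and can push the left limit above
the right limit; a bisection on $\varepsilon$ resolves the cases where
this binds). The result: dip 0 for constant samples, $1/(2n)$ for
perfectly unimodal-looking samples, $1/4$ in the two-point-mass limit.
The test suite verifies the implementation against an independent oracle
that encodes the definition directly as small convex feasibility programs
(quadprog), over a battery of shapes including clusters and ties, and
checks the bootstrap test's size against its nominal level under the
uniform null.

## Evolutionary statistics

- **Generations.** A 1:$D$ dilution regrown to saturation contributes
  $\log_2 D$ generations; 100 µL into 9.9 mL daily gives 6.64
  generations/day, ~199 over 30 days.
- **Fitness.** Malthusian parameter $m = \ln(N_f/N_0)$ per cycle;
  selection rate constant $r_{ij} = (m_i - m_j)/\text{duration}$ in
  1/day. $r_{ij} = -r_{ji}$ exactly, and $m$ is invariant to the density
  unit.
- **Invasion.** Per (condition, starting frequency), a one-sample
  two-tailed $t$ test of $r$ against zero across replicates. A genotype
  invades from rare when its $r$ at rare frequencies (≤ 0.10) is
  significantly positive; a pair stably coexists when both invade when
  rare. With two conditions the per-replicate $r$ values pooled across
  frequencies are compared by a Welch two-tailed $t$ test (the canonical
  5-frequencies × 3-replicates design gives 15 vs 15 values, ~28 degrees
  of freedom).
- **Mutation filtering.** Records below 5% population frequency are
  dropped (at-or-above keeps the boundary); frequencies reported as
  "<5%" in source tables are coded 0.04 with a censoring flag.
- **NS/S.** (nonsynonymous + nonsense) / synonymous over point mutations
  only, with an explicit flag instead of a division by zero when no
  synonymous mutation was observed.
- **Parallelism.** Under uniform-per-bp placement of $T$ observed
  mutations on a genome of $G$ bp, a gene of length $L$ expects
  $\lambda = T L / G$ hits; the gene-level parallelism $p$ value is the
  Poisson upper tail $P(X \ge x)$, computed by direct term-by-term
  summation so that tails of order $10^{-11}$ retain full relative
  precision (cross-checked against `ppois(lower.tail = FALSE)`).
  The genome size is configuration (default 6,181,863 bp, the
  *P. putida* KT2440 reference); indels are excluded from $T$ by default
  and no multiplicity correction is applied unless requested — both
  toggles exist. For the canonical worked example (4 hits in a 1476-bp
  gene, 29 point mutations) this gives $\lambda = 6.92\times10^{-3}$ and
  $p = 9.5\times10^{-11}$.
- **Sweeps.** Frequency ≥ 0.99 is classed `fixed` (absorbing the rounding
  of frequencies reported as "100%"), ≥ 0.10 `high`, otherwise `low`.
- **Biofilm.** Index = crystal-violet OD595 / culture OD600; replicate
  sets are compared with the same Welch test as any other trait.

## The synthetic-data generators

The generators exist so that every analysis stage is testable without any
sequencing download, and they emulate exactly the statistical structure
the analyses assume: Monod batch curves with multiplicative lognormal OD
noise floored at the instrument resolution; mutation tables with
uniform-per-bp placement (the parallelism null) plus an optional enriched
gene; competition assays as deterministic co-growth on a shared pool with
lognormal count noise at the canonical frequency panel
{5, 10, 50, 90, 95}%; and two-species transfer series with injected
mutants. Everything is seeded, and identical seeds give identical output.

What they deliberately do not emulate: reads or genome sequences (mutation
tables are generated at the table level), lag phases and diauxie in growth
curves, pH or temperature effects, within-cycle spatial structure, and
mutational input during the simulation (mutants appear by injection at a
configured day, not by a mutation process). Passing tests therefore show
that the analyses do what they claim on data obeying their own
assumptions; they do not validate those assumptions against wet-lab data.

## The demonstration scenarios

`run_full_demo()` wires everything together under one seed. The
monoculture scenario gives the focal consumer a small residual-carbon
pulse (0.12 mM, five-fold below the co-culture supply — the medium is not
perfectly carbon-free) and injects a 3.4-fold-higher-yield mutant on day
6; the mutant sweeps to the `fixed` class and the ancestor falls below
detection. The co-culture scenario keeps a cross-feeder and two consumer
morphotypes; the two morphotypes persist above detection for all 30 days
and an end-point sample of clone yields is bimodal by the dip test, while
the monoculture sample is not.

Coexistence in the co-culture scenario is encoded *phenomenologically*:
the minority morphotype draws on a partially private resource pool. The
mechanism that maintains two morphotypes in the real community is an open
question (the reciprocal-invasion analysis in this package is exactly the
tool that failed to confirm frequency-dependent selection as the
mechanism), so the simulator does not hard-code any particular answer;
the private-pool toggle is one convenient way to obtain stable
coexistence and is labelled illustrative wherever it is used.

Scenario parameters that are modelling choices rather than measurements:
cross-feeder kinetics ($Y$ 0.04 OD/mM, $V$ 8 mM/OD/h, $K$ 0.05 mM), leak
fraction 1.0, OD↔CFU factor 5×10⁸, residual-carbon pulse 0.12 mM, the
private-niche capacity (3.2 mM substrate-equivalents, set so the
co-culture end point sits near a 64:36 small:large morphotype split — the
large morphotype is the minority in the community this emulates), consumer
uptake rates chosen so that daily 1:100 regrowth completes within a cycle
(a genotype with $\mu_{\max}\,T < \ln D$ washes out by arithmetic, which
is also a useful negative control: setting the leak fraction to zero
collapses the benzoate consumers).

## Numerical and testing choices

Problem sizes were chosen to keep the whole default test run in minutes on
one core: 20 parameter sets for the noiseless round trip, 100 noise seeds
for the noisy one, 10⁴ tables for the parallelism null calibration, 500
samples (n = 50, against a shared 2000-draw null) for the dip-test size
check, 200 simulations for invasion power, 2000 bootstrap draws and
60-clone samples for the demonstration dip tests. The dip oracle
comparison runs on small samples (n ≤ 10) where the convex programs stay
tiny.

Known limitations, beyond the generator scope above: the trait pipeline
assumes single-resource, lag-free curves (no diauxie, no logistic/Gompertz
alternatives); $K$ is weakly identified by design-typical curves (see
above); the GenomeDiff reader covers the SNP/INS/DEL mutation subset only
and requires gene names/lengths as attributes (no annotation lookup); and
the invasion verdict follows the significance convention at $\alpha =
0.05$ per cell without multiplicity correction across frequencies.
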