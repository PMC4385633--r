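---
title: "Methods: agent-based simulation of enzymatic reactions and virtual kinetics assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: agent-based simulation of enzymatic reactions and virtual kinetics assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzsim)
```

## The model

`enzsim` represents a patch of intracellular space as a continuous
two-dimensional rectangle whose boundary acts as the cell membrane. Every
molecule of interest is an individual circular agent with a species-specific
radius and diffusion rate; molecules too numerous to represent individually
(water, small ions, the bulk of the proteome) are summarised by immobile
"obstacle" agents that deflect everything else. Because the arena is a 2D
slab standing in for a thin volume, laboratory concentrations map to agent
counts through an assumed slab height:

$$ N \;=\; \mathrm{round}\!\left( C \cdot N_A \cdot A \cdot h \right), $$

with $C$ the molar concentration, $N_A$ the Avogadro constant, $A$ the
arena area (µm²) and $h$ the assumed height (default 0.005 µm, the height
of a typical enzyme; the product $A\,h$ is in µm³ = 10⁻¹⁵ L). Rounding is
half-away-from-zero, so 4.98×10⁻¹ mM in a 1 µm² × 0.005 µm slab is exactly
1500 molecules. One simulation tick represents a configurable number of
seconds (`seconds_per_step`, default 10 s).

### Geometry from molecular mass

When a species' radius or diffusion rate is not supplied, it is derived
from molecular mass. Radii follow a power law
$r = r_\mathrm{ref} (M/M_\mathrm{ref})^\alpha$ anchored at benzyl alcohol
(108.14 g/mol, 0.323×10⁻³ µm) with $\alpha$ fitted by least squares on
log–log rows that carry explicit radii; the two bundled anchor rows
(benzyl alcohol and NAD⁺) give $\alpha \approx 0.392$. Diffusion rates use
Stokes-like inverse-radius scaling $D = D_\mathrm{ref}\, r_\mathrm{ref}/r$.
These two rules jointly reproduce the bundled pathway table (radii to 3
significant figures, diffusion rates to 4, benzaldehyde's diffusion within
one unit in the last digit) — that agreement is what justifies the choice
of functional forms, since only the tabulated values, not the original
correlation, are available.

### Movement and collisions

The *distance unit* is the radius of the smallest mobile species. Each
tick, every idle mobile agent advances along its heading by
$s = d_\mathrm{unit} \cdot D / D_{\max}$, so the fastest species moves
exactly one distance unit per tick and slower species proportionally less.
This deliberately treats the printed diffusion rates as *relative*
velocities (their absolute magnitudes, ~10⁻¹⁴ µm²/s, are game-scale
values); real time enters only through `seconds_per_step`. An
Einstein-relation step $\sqrt{4 D \Delta t}$ would be the alternative, but
it has no consistent calibration against the printed values.

Two circles collide when their centre distance is *strictly* less than the
sum of their radii (exact tangency is contact, not collision). Collision
detection uses a uniform spatial grid with cell size at least twice the
largest radius, which is exact — the test suite asserts identity with a
quadratic all-pairs scan over thousands of random configurations.

On a collision with no applicable rule, agents are reoriented: the heading
of each *approaching* agent is specularly reflected about the contact
normal, a uniform angular jitter in $[-\theta_j, \theta_j]$ (default
$\theta_j = 0.2$ rad, configurable) is added, and the pair is pushed apart
along the normal to exact tangency. The jitter restores diffusive
behaviour statistically on top of the otherwise ballistic, heading-
persistent motion. The exported `reflect_heading()` helper applies the
pure mirror law unconditionally; inside the engine only agents moving
toward the contact are reflected, so that an agent already departing is
not turned back into its partner. The jitter is independent of the
diffusion rate; the reorientation hook would be the place to make it
diffusion-dependent, but no specification of that dependence exists, so
the simplest rule is used.

At the membrane (the arena boundary) an agent is, by species: *reflected*
(default), *reconverted* — replaced in place by another species, the rule
used for NADH recycling to NAD⁺ — or *excreted*, removed from the arena
with a cumulative exported counter (benzoate in the bundled pathway).

### The behavioural rulebook

One tick applies, in order: (1) influx batches; (2) movement of all mobile
agents in seeded-shuffled order, with membrane actions on boundary
crossing; (3) collision detection on post-move positions; (4) resolution
of colliding pairs in seeded-shuffled order; (5) completion of reactions
whose duration ends this tick; (6) recording of per-species counts and
cumulative event counters. Each agent participates in at most one
rule-triggering event per tick; the shuffled pair order decides which rule
fires in multi-contact pileups, and non-reactive contacts still reorient.

* **Cofactor binding**: an enzyme colliding with its required cofactor is
  replaced, together with the cofactor, by a single holoenzyme agent at
  the enzyme's position and heading. Holoenzymes inherit the enzyme's
  geometry unless their species row overrides it.
* **Catalysis**: a catalyst (holoenzyme or bare enzyme) colliding with its
  substrate reacts with probability `p_react`; the substrate disappears
  immediately and the catalyst becomes busy for `duration_steps` (τ)
  ticks. On completion the catalyst is replaced by the full product side
  (regenerated enzyme, converted cofactor, products) at its position with
  random headings. τ = 0 completes within the same tick. While busy, the
  complex keeps moving but ignores all collisions except membrane
  reflection — the least-assumption choice for an unspecified interval.
* **Influx**: `influx_schedule()` introduces a species gradually (e.g.
  10% of 1500 molecules every 10 ticks). Batch sizes use cumulative
  rounding, so they always sum exactly to the scheduled total.
* Protons and water on the product side of the bundled pathway reactions
  are not instantiated as agents; sub-resolution species are represented
  only in aggregate by the obstacles.

Determinism: all randomness (placement, headings, shuffles, reaction
draws, jitter) comes from R's RNG; a world carries its own RNG state, so
an identical scenario and seed give bit-identical time series.

## The virtual kinetics assay

The assay mimics the laboratory protocol for measuring Michaelis–Menten
kinetics. For substrate concentration $S$,

$$ V = \frac{V_{\max} S}{K_m + S}, \qquad
   \frac{1}{V} = \frac{K_m}{V_{\max}}\frac{1}{S} + \frac{1}{V_{\max}},
   \qquad k_{\mathrm{cat}} = \frac{V_{\max}}{[E]}. $$

`run_assay()` simulates each substrate concentration `replicates` times
(default 3) with seeds derived from the design's base seed, measures the
initial velocity as the OLS slope of product concentration against real
time over the first `measurement_window` ticks (default 500), averages
velocities per concentration, and fits the double-reciprocal regression of
$1/V$ on $1/S$: $K_m$ = slope/intercept, $V_{\max}$ = 1/intercept,
$k_{\mathrm{cat}} = V_{\max}/[E]$. Negative estimates — which arise when
the intercept is small and noise-dominated — are reported unmodified, and
are excluded only from reference matching.

Defaults mirror the bundled single-reaction setting: a 1 µm² arena,
enzyme at 4.98×10⁻² mM (150 agents), five substrate levels from
6.64×10⁻² to 6.64×10⁻¹ mM (200–1999 agents), 10 s per tick. The enzyme's
geometry is not tabulated anywhere, so the package assigns a typical
dehydrogenase-subunit mass of 4×10⁴ g/mol and derives radius and diffusion
from the scaling laws; consequently the assay's *absolute* $K_m$ and
$k_{\mathrm{cat}}$ magnitudes are a property of this package's geometry,
and only directional trends are comparable across implementations.

`parameter_scan()` repeats the assay over a grid of
(`p_react`, `duration_steps`) with per-cell seeds derived from the cell's
own coordinates (results are independent of iteration order).
`match_to_reference()` compares a scan table against experimentally
characterised enzymes by the scaled Euclidean distance
$\sqrt{(\Delta K_m/K_m^{\mathrm{ref}})^2 +
       (\Delta k_{\mathrm{cat}}/k_{\mathrm{cat}}^{\mathrm{ref}})^2}$,
chosen so both constants weigh equally across magnitudes; rows with
negative estimates are excluded.

## Bundled scenarios and what the synthetic runs emulate

`generate_fixture("two_step_pathway")` builds the two-enzyme benzyl
alcohol oxidation pathway: aryl-alcohol dehydrogenase (EC 1.1.1.90) and
benzaldehyde dehydrogenase (EC 1.2.1.28), each at 1.66 mM (~5×10³
agents at scale 1), NAD⁺ at 33.2 mM, NADH at 3.32 mM, 10⁵ obstacles, and
a gradual influx of 1500 benzyl alcohol molecules (10% every 10 ticks).
NADH recycles to NAD⁺ at the membrane; benzoate is excreted. The two
reaction probabilities and durations are not tabulated; the fixture uses
p = 0.75, τ = 25 ticks, the midrange of the "common scenario" settings
explored by the assay. The `scale` argument multiplies all counts and the
arena area by the same factor, preserving every concentration, so reduced
runs keep full-scale per-agent rates.

These synthetic runs emulate the *mechanistic* features of the real
system — holoenzyme formation as a prerequisite for catalysis, cofactor
cycling through the membrane, sequential appearance of the intermediate
and the excreted product — at realistic counts. They do not emulate 3D
geometry, reversible reactions or inhibition, temperature/viscosity
effects on diffusion, or localised membrane transport (influx is uniform
over the arena). Passing tests therefore demonstrate internal consistency
and qualitative fidelity of the rule system, not quantitative prediction
for real cells.

## Numerical choices and problem sizes

* Collision test strict (`<`); separation pushes to tangency plus a 10⁻⁹
  relative epsilon so separated pairs do not immediately re-collide.
* Coincident centres (distance 0) get a random contact normal.
* Placement is rejection-sampled (100 attempts) against overlap; in an
  over-crowded arena the last candidate is accepted, so initialisation
  always terminates.
* Counts round half away from zero; influx batches use cumulative
  rounding.
* The zero-velocity case (no product in the window) is a hard error in
  the Lineweaver–Burk fit naming the offending concentration, because its
  reciprocal is undefined; widen the window or raise `p_react` to avoid
  it.
* Test problem sizes: the conservation and determinism suite runs the
  two-step pathway at scale 0.01 (≈2200 agents) for 10³ ticks over 5
  seeds; the qualitative-dynamics run uses scale 0.05 (≈11 000 agents)
  for 600 ticks — the horizon spans the pathway's own timescale (influx
  ends at tick 91, the intermediate peaks near tick 200, excretion is
  under way well before tick 600). Directional assay checks use the full
  default assay composition (150 enzymes, 200–1999 substrate agents)
  with the default 500-tick window over 5 seed groups.
* The crowding check contrasts 0 vs 10⁵ obstacles in a sparse-enzyme
  (transport-limited) scenario: at 10³–10⁴ obstacles the effect on the
  reaction rate is smaller than seed-to-seed noise, and large obstacles
  can even *raise* the rate through excluded-volume concentration, so the
  test asserts the contrast at the density where deflection-limited
  transport demonstrably dominates.

## Known limitations

* **Unsaturated assay regime.** With the tabulated small-molecule
  geometry and the derived enzyme geometry, the per-enzyme reactive
  encounter rate is λ ≈ 3×10⁻³ per tick, so even at τ = 100 the busy
  fraction stays below ~25%. The Lineweaver–Burk intercept (τ/[E] in
  expectation) is then comparable to its sampling noise: $k_{\mathrm{cat}}$
  estimates at fixed p are only weakly ordered in τ, and at τ = 0 the
  intercept is essentially pure noise, making $K_m$ = slope/intercept
  sign-unstable. Directional comparisons across `p_react` at τ = 0 are
  therefore unreliable at these problem sizes; trends across τ ≥ 25
  emerge as windows lengthen. This is a property of the modelled
  geometry, not of the estimator (which is exact on noiseless input).
* Reference matching is a pure argmin under the scaled Euclidean metric;
  visually-guided pairings of noisy scan tables need not coincide with
  it.
* Ballistic-with-jitter motion is not true Brownian motion; its
  effective diffusivity depends on the collision environment.
* 2D only; the slab height enters the unit conversion but not the
  dynamics.
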