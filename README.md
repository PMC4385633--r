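# enzsim

Agent-based spatiotemporal simulation of biomolecular reactions, with a
virtual assay that recovers Michaelis–Menten kinetics from collision
statistics.

## What it is for

Bulk enzyme kinetics hides everything spatial: crowding, cofactor
availability, membrane transport, the sheer granularity of a few hundred
molecules in a square micron. `enzsim` is for systems/computational
biologists who want to study those effects explicitly. Every molecule is a
circular agent diffusing in a continuous, membrane-bounded 2D arena;
collisions — detected by the circle-overlap rule
`distance(centres) < r₁ + r₂` — drive a behavioural rulebook: enzymes bind
their cofactor into a holoenzyme, holoenzymes catalyse substrates with a
per-collision probability `p_react` and a reaction duration τ (ticks),
NADH recycles to NAD⁺ at the membrane, products can be excreted, inert
obstacles emulate molecular crowding, and substrates can flow in
gradually.

Laboratory units map to simulation units through
`N = round(C · N_A · A · h)` (concentration `C` in a slab of area `A` and
assumed height `h` = 0.005 µm), and particle geometry derives from
molecular mass via a fitted power law for radius
(`r ∝ M^0.392`) with Stokes-like inverse-radius diffusion scaling.

On top of the simulator sits the kinetics pipeline: measure initial
velocities of product formation across substrate concentrations, fit the
Lineweaver–Burk double-reciprocal regression

```
1/V = (K_m/V_max)·(1/S) + 1/V_max ,   k_cat = V_max/[E]
```

scan the (`p_react`, τ) grid, and match scan rows against experimentally
characterised enzymes.

## Worked example

Unit conversion: 4.98×10⁻¹ mM of benzyl alcohol in a 1 µm² × 0.005 µm
slab is exactly 1500 molecules.

```r
library(enzsim)
u <- unit_system(arena_area = 1, assumed_height = 0.005, seconds_per_step = 10)
concentration_to_count(4.98e-1, u)
#> [1] 1500
```

The bundled two-step pathway (benzyl alcohol → benzaldehyde → benzoate,
catalysed by two NAD⁺-dependent dehydrogenases, 10⁵ crowding obstacles at
full scale) at 5% scale, 600 ticks:

```r
sc  <- generate_fixture("two_step_pathway", scale = 0.05)
sim <- simulate_scenario(sc, steps = 600, seed = 1)
sim
#> enzsim simulation: 600 ticks, seed 1
#> final counts: benzyl_alcohol 9, NAD 4440, NADH 558, benzaldehyde 15,
#>   benzoate 47, aadh 0, badh 0, holo1 250, holo2 250, obstacle 5000
#> reactions completed: oxidation1 66, oxidation2 50

sim$series[sim$series$tick %in% c(100, 300, 600),
           c("tick", "n_benzyl_alcohol", "n_benzaldehyde", "n_benzoate", "ex_benzoate")]
#>     tick n_benzyl_alcohol n_benzaldehyde n_benzoate ex_benzoate
#> 101  100               45             18          0           0
#> 301  300               18             32         20           0
#> 601  600                9             15         47           3
```

Reading this: the influxed substrate decays as the first reaction consumes
it, the intermediate benzaldehyde rises and then falls as the second
enzyme takes over, benzoate accumulates, and by tick 600 three benzoate
molecules have hit the membrane and been excreted. Both enzymes sit fully
in holoenzyme form (`aadh 0, holo1 250`) because NAD⁺ is abundant.

A virtual assay at `p_react = 0.75`, τ = 25 ticks (five substrate levels,
three replicates each, velocities measured over the first 500 ticks):

```r
res <- run_assay(assay_design(p_react = 0.75, duration_steps = 25L, base_seed = 1L))
res
#> Lineweaver-Burk fit (5 concentrations)
#>   Km   = 2.54212 mM
#>   Vmax = 5.00788e-05 mM/s
#>   kcat = 0.0010056 1/s
#>   slope = 50762.5, intercept = 19968.5, R^2 = 0.9962
```

`Km` is the substrate concentration at half-maximal velocity (lower =
tighter apparent binding, driven here by `p_react`); `kcat` the turnover
number per enzyme per second (driven by τ). Absolute magnitudes depend on
the assay's species geometry — see the methods vignette
(`vignettes/enzsim-methods.Rmd`) for why only directional trends are
comparable across implementations.

Reference matching against the bundled table of six characterised enzymes:

```r
match_to_reference(example_scan_table(), reference_enzymes())
```

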