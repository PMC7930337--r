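# wormCPG

Can *Caenorhabditis elegans* crawl forward using nothing but a chain of
**network oscillators** in its ventral nerve cord — no stretch-receptor
feedback, no pacemaker neurons, no descending command input? `wormCPG`
implements a neuromechanical model built to answer that question, for
computational neuroscientists and systems biologists studying locomotion:

* the repeating seven-class motorneuron unit (AS, DA, DB, DD, VA, VB, VD)
  as a continuous-time recurrent neural network, seven units chained by two
  interunit chemical synapses (DB→DD⁺¹, VA⁺¹→DD) and three gap junctions
  (DA⊣⊢AS⁺¹, VB⊣⊢DB⁺¹, AS⊣⊢VA⁺¹) — 49 neurons,

  τᵢ dVᵢ/dt = −Vᵢ + Σⱼ wⱼᵢ σ(Vⱼ+θⱼ) + Σⱼ gⱼᵢ (Vⱼ−Vᵢ),  σ(x) = 1/(1+e⁻ˣ)

* 24 dorsal + 24 ventral leaky-integrator muscles (τ_M = 100 ms) with
  Hill-type force-length/velocity properties, driven through
  I_m = Σ γ_m qᵢ Sᵢ with an evolved anterior-posterior gain gradient
  γ_m = 0.7(1−(m−1)F/24),

* a 2D rod-and-spring body (50 segments, 153 DOF) in the overdamped agar
  regime, F = −Cv with C∥ = 3.2×10⁻³ and C⊥ = 128×10⁻³ kg/s, integrated
  semi-implicitly at 0.1 ms,

* the two-stage genetic algorithm over the 44-parameter genotype
  (fitness F₁ for isolated-unit rhythms at 0.44 Hz, F₁·F₂ for embodied
  crawling at 0.22 mm/s), and

* the analysis suite: curvature kymographs, kinematic ensemble filters,
  regional paralysis and gap-junction overexpression experiments,
  subcircuit oscillation scores, interunit necessity/sufficiency, and
  entrainment/phase-shift measures.

The methods vignette (`vignettes/worm-locomotion-model.Rmd`) documents the
model, every default constant, and the package's design choices.

## A worked example

Evolve an isolated ventral-nerve-cord unit into a rhythmic pattern
generator, then inspect it:

```r
library(wormCPG)
cfg <- wcpg_config()

res <- evolve_stage1(seed = 1, cfg)      # a few minutes on one core
res$fitness
#> [1] 0.9942766

tr <- run_isolated_unit(res$genotype, cfg)          # 50 s, 10 s transient
estimate_frequency(neuron_trace(tr, "DB"), tr$dt)
#> [1] 0.4400135
#> attr(,"oscillatory")
#> [1] TRUE
```

The evolved unit oscillates with full-amplitude B-class output at the
bending frequency of crawling worms (0.44 Hz), so the stage-1 fitness — the
product of a total-variation amplitude term (capped at 1) and a frequency
match term — is above the 0.99 success threshold.

The committed demo locomotor (a stage-2 product) crawls when embodied:

```r
worm <- demo_genotype("locomotor")
tr <- run_embodied(worm, cfg, duration = 30)
win <- trace_window(tr, from = 10)
mean_velocity(win)            # net COM progression, mm/s
#> [1] 0.0770872
kym <- curvature_kymograph(win)
body_wavelength(kym)          # body lengths; the ensemble filter wants 0.4-0.9
#> [1] 0.5181406
#> attr(,"oscillatory")
#> [1] TRUE
#> attr(,"pass")
#> [1] TRUE
```

The demo worm crawls forward at 0.077 mm/s with a posterior-traveling
bending wave of ~0.52 body lengths, passes all three ensemble filters
(B-class NMJ dependence, body curvature, trajectory straightness), keeps
bending in the tail when the three anterior units are paralysed, and is
paralysed by B-class gap-junction overexpression — the qualitative
signatures of the network-oscillator mechanism. Its speed sits below the
0.22 mm/s biological target: the body's synthetic spring/muscle calibration
tops out around 0.15 mm/s (see the vignette's limitations section).

Masks reproduce the experimental manipulations, e.g. anterior paralysis
(`circuit_masks(nmj_off_units = 1:3)`) or B-class gap-junction
overexpression (`circuit_masks(gj_B_factor = 8)`).

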