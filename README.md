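# nucsim

Stochastic lattice simulation of nucleosome positioning around
transcription start sites (TSS).

## The problem

Metagene nucleosome-density profiles behave differently across species as
transcription increases: in budding yeast the phased array downstream of
the TSS *loses* amplitude on active genes, while in mouse embryonic stem
cells clear oscillations *emerge* from a featureless profile.  `nucsim`
implements a minimal kinetic model that reconciles these observations by
combining four ingredients on a one-dimensional DNA lattice:

1. **Thermal diffusion** of nucleosomes (hard rods of 147 bp tracked by
   their dyad `x_i`), hopping ±1 bp at rate
   `d = D/Δl² · exp(−βΔU/2)` with `D = 1 bp²/s` — detailed balance.
2. **A promoter barrier**: a triangular repulsive potential (apex 25 kBT at
   −150 bp, support [−300, 0]) standing in for transcription factors and
   the preinitiation complex; it creates the nucleosome-depleted region and
   drives statistical positioning of the downstream array.
3. **Spacer enzymes** (ISW1/Chd1-like): any neighboring pair with dyad
   distance in [148, 332] bp is remodeled at rate `k` (0.08–0.16 s⁻¹),
   moving one nucleosome 1 bp toward the other *independently of the
   energy landscape* — this breaks detailed balance and condenses the
   array against the barrier, delocalizing the +1 nucleosome.
4. **Histone exchange** (Pol II-driven eviction/redeposition):
   absorption/desorption with rates
   `r_on = r · exp(−βΔV/2)`, `r_off = r · exp(+βΔV/2)`, `ΔV = ΔU + μ`,
   where the chemical potential μ is calibrated so the accessible lattice
   (14 401 bp outside the barrier, ≈ 98 footprints) holds a mean density
   of 0.88.

All dynamics run through one exact (Gillespie) event-driven engine written
in C++.  The non-equilibrium spacer kinetics can be folded into an
equilibrium description as a short-range nearest-neighbor attraction
`u_eff(g)`; `effective_pair_potential()` calibrates that attraction
against direct kinetics on a reduced lattice, and the fast
absorption/desorption sampler (`r = 12 s⁻¹`) then reproduces the
steady state at a fraction of the cost — including the hallmark
phenomenology: barrier-only profiles with decaying peaks ("yeast-like"),
enzyme-condensed profiles whose peaks *grow* with distance from the TSS
("mouse-like"), a −2 kBT positioning well (INO80-like) that restores
yeast-like order, and fast exchange that erases the enzyme signature.

The analysis layer provides TSS-anchored normalized density profiles,
kernel smoothing, radial distribution functions, peak-based spacing
estimates, +1-ordered configuration heatmaps, a yeast/mouse profile
classifier, a phase-diagram scan, a sequence-affinity module based on
dinucleotide periodicity (10.1-bp phased AA/TT/TA/AT vs anti-phased GC),
and a single-molecule pipeline for +1-nucleosome heterogeneity in
fragment tables.

## Worked example

A reduced (2 940 bp) barrier-only system, calibrated and sampled in about
a minute:

```r
library(nucsim)

lat   <- lattice_spec(length_bp = 2940, tss_index = 500)
field <- energy_field(lat, barrier = make_barrier(lat))
model <- kinetic_model(field, D = 0, r_const = 12)

mu <- calibrate_mu(model, target_density = 0.88, seed = 1)
round(as.numeric(mu), 2)
#> [1] 40.22

model <- kinetic_model(field, D = 0, r_const = 12, mu = as.numeric(mu))
rec <- sample_equilibrium(model, simulation_protocol(
  n_replicas = 2, t_end = 3000, burn_in = 500,
  sample_interval = 2, initial_n = 16, seed = 7))
rec
#> <ensemble_record> 2500 samples, 2 replica(s), lattice 2940 bp
#>   bound nucleosomes: mean 15.9, range [13, 17]

prof <- smooth_profile(density_profile(rec, window = c(-500, 1200)),
                       bandwidth = 10)
head(find_peaks(prof, from = 0), 3)
#>   offset   height prominence
#> 1      6 3.431782  0.2342141
#> 2    177 2.127668  1.7912787
#> 3    347 1.779841  1.2287312
classify_profile(prof)
#> [1] "yeast_like"
round(mean_spacing(prof, n_peaks = 5), 1)
#> [1] 169.2
```

The chemical potential of ~40 kBT balances the −42 kBT binding free
energy to hold ~16 nucleosomes (density 0.88 of the accessible region;
the bound count fluctuates by only ±2).  The profile shows a contact peak
where the array presses against the barrier edge, then a phased array
with ~170-bp repeat whose peaks decay away from the TSS — statistical
positioning, classified yeast-like.  Swapping in
`effective_pair_potential(0.16)` condenses the array and flips the
classification to mouse-like; see the methods vignette
(`vignettes/nucsim-methods.Rmd`) for the full scenario tour.

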