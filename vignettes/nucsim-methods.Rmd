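---
title: "Modeling nucleosome positioning near transcription start sites with nucsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling nucleosome positioning near transcription start sites with nucsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nucsim)
```

## The model

`nucsim` simulates nucleosomes as hard rods on a periodic one-dimensional
lattice of base pairs.  A nucleosome is tracked by its dyad (footprint
center); the footprint spans `[dyad - 73, dyad + 73]` and two dyads may
never be closer than 147 bp.  Energies are in units of kBT throughout
(β = 1).  The total energy of a configuration is

* a per-bp binding energy `V_s` summed over each footprint — uniform at
  −42/147 per bp by default, so one nucleosome binds with −42 kBT, or
  sequence-derived (see below);
* a dyad-evaluated triangular **promoter barrier** (apex height 25 kBT at
  −150 bp from the TSS, falling linearly to zero at −300 and 0) modeling
  the competition of transcription factors, the preinitiation complex and
  Pol II with histones.  Evaluating it at the dyad only keeps the penalty
  finite, so nucleosomes retain a small but nonzero probability of
  occupying the promoter, and leaves an accessible region of
  14 700 − 299 = 14 401 bp ≈ 98 footprints;
* a dyad-evaluated flat **positioning well** (default −2 kBT on
  [0, 30] bp), a coarse stand-in for positioning remodelers that pull the
  +1 nucleosome toward the TSS;
* an optional nearest-neighbor **pair attraction** `u_eff(gap)` used by
  the accelerated sampler (below).

Four event classes drive the continuous-time Markov dynamics, simulated
exactly with the Gillespie algorithm (compiled engine, incremental rate
bookkeeping, a segment tree over absorption sites; the from-scratch event
enumeration in R is kept as the reference the engine is tested against):

| event | rate |
|---|---|
| 1-bp hop | `D/Δl² · exp(−ΔU/2)`, `D = 1 bp²/s`, `Δl = 1 bp` |
| spacer remodeling, per pair with gap in `[148, 332]` | `k` (0–0.16 s⁻¹), mover drawn by coin flip, energy-independent |
| desorption | `r · exp(+ΔV/2)` |
| absorption at any free-footprint site | `r · exp(−ΔV/2)` |

with `ΔV = ΔU + μ`.  Hops and exchange satisfy detailed balance by
construction (`r_on/r_off = exp(−ΔV)` exactly); the spacer moves do not,
which is the point: they are the model's only non-equilibrium ingredient.

## Why the barrier is essential to the spacer-enzyme effect

A spacer event shrinks the gap it acts on by 1 bp and grows an adjacent
gap by 1 bp.  In a homogeneous ring the two fluxes cancel on average, so
bulk gap statistics are nearly unchanged at realistic rates — we verified
that at `k = 0.16 s⁻¹`, `D = 1 bp²/s` and density 0.85 the ring gap
distribution is indistinguishable from the `k = 0` equilibrium over 10⁶
simulated seconds.  Against a boundary the cancellation fails: the pair
nearest the barrier feeds linker into the nucleosome-free region and
nothing feeds back, so the array compacts from the edges inward.  This is
why the condensed, "mouse-like" profiles require both the barrier and the
enzymes, and it dictates how we calibrate the effective attraction.

## The enzyme-renormalized attraction and its calibration

For sampling purposes the non-equilibrium spacer kinetics is replaced by
an equilibrium system with a short-range nearest-neighbor attraction.
`effective_pair_potential(k)` obtains it by calibration rather than from
a closed form:

1. run the full diffusion + enzyme kinetics at fixed N on a 1/5-scale
   lattice (2 940 bp) carrying the standard barrier, N = 16 (density 0.88
   of the accessible region), 2 replicas × 3 × 10⁵ s (the boundary-driven
   compaction converges within about half that);
2. record the distribution of *interior* gaps — the pair spanning the
   barrier apex is excluded, since that gap is the nucleosome-free region;
3. fit a piecewise-linear well `u(g) = −depth · (1 − (g − 147)/width)` on
   `[147, 147 + width]`, `width ≤ 185` so the attraction vanishes beyond
   the 332-bp enzyme range, by matching the exact interior-gap
   distribution of a bounded-segment rod model computed by FFT
   convolution (`segment_gap_marginal()`).  A `k = 0` control run fixes
   the effective segment length, absorbing the softness of the triangular
   barrier edges.

The fits give depth ≈ 9.7 kBT over 138 bp for `k = 0.16 s⁻¹` and
≈ 7.4 kBT over 185 bp for `k = 0.08 s⁻¹` — in both cases a shallow
*slope* of roughly `k/2D` per bp at contact, which is the drift-diffusion
balance one expects: the enzyme pushes a gap inward at `k` bp/s while the
gap diffuses with coefficient ~2D.  Any renormalized temperature is
folded into the single energy table, since only energy ratios enter the
rates.  The defining contract is checked directly in the test suite:
the absorption/desorption sampler under `u_eff` reproduces the interior
gap statistics and profile shape of the full kinetics at reduced scale,
and the enzyme-rate ordering of mean gaps survives at production scale.

## Calibrating the chemical potential

`calibrate_mu()` targets a mean density of 0.88 — the occupied fraction
of the *accessible* region, so on the full lattice the target is
0.88 × 98 ≈ 86 bound nucleosomes.  Under the fitted attraction the
density–μ curve is steep (the array behaves like a self-bound droplet and
evaporates over a few kBT of μ), and short stochastic runs carry ~0.01
density noise, so plain secant iteration is unreliable.  The
implementation instead computes the exact grand-canonical number weights
of the bounded-segment model by convolution
(`segment_number_weights()`), starts from the μ that puts the analytic
mean at target, and refines with stochastic Newton steps whose slope is
the analytic `d⟨N⟩/dμ = −Var(N)`.  In practice the analytic start lands
within tolerance (|density − 0.88| ≤ 0.01 ≈ one nucleosome) on the first
measurement for both the hard-core and the attractive models; every
iterate is logged in the returned `trace` attribute.

## Simulation protocols and scaled-down sizes

The production scenarios all use the 14 700-bp periodic lattice.  The
accelerated sampler runs absorption/desorption only at `r = 12 s⁻¹`; the
explicit Pol II scenario runs diffusion + enzymes + exchange at
`r = 0.1 s⁻¹` (a one-per-ten-minutes eviction scale) with μ taken from
the bare-potential calibration, since the exchange rates obey detailed
balance with respect to the bare potential and dominate the steady
state.  Relaxation under exchange is set by the eviction time
(tens to hundreds of seconds), not by jammed one-dimensional diffusion,
so trajectories of a few thousand seconds reach steady state.

This package's standard ensembles are 2–3 replicas × 3 500–6 000 s with
samples every 2 s after a 1 000-s burn-in (2 500–5 000 configurations per
ensemble, tens of thousands of gaps), chosen so that profile peak heights
carry ~2–3 % noise after 10-bp Gaussian smoothing — sufficient for every
comparison the package makes.  The bounded-segment convolution oracles
and the exhaustive small-lattice enumerations (`enumerate_reference()`,
≤ 3 rods on ≤ 588 bp) back the statistical tests at exactly solvable
scale.

## Analysis layer conventions

* **Density profiles** count dyads per bp offset from the TSS, averaged
  over samples and divided by the lattice-wide mean dyad density, so
  featureless regions sit at 1.  The analysis window defaults to
  [−500, 1500] bp at 1-bp bins.
* **Smoothing** is linear with a named kernel (Gaussian, sd 10 bp by
  default, truncated at 4 sd and renormalized at window edges, so
  constants are preserved exactly); the raw profile is retained.
* **Peak detection** takes strict local maxima filtered by topographic
  prominence (≥ 5 % of the profile range) and a 100-bp minimum
  separation, ties broken leftmost.  All three parameters are exposed;
  the spacing estimate is the mean distance between the first five
  downstream peaks.
* **Classification** compares the first two downstream peaks:
  second higher → `mouse_like`, lower → `yeast_like`, equal within 2 %
  (relative) → `boundary`.
* **RDF** normalizes pairwise dyad distances so a homogeneous ideal
  system gives g(r) = 1; g(r) = 0 below 147 bp by exclusion.
* **Gap statistics** (`ensemble_gaps()`) exclude the pair spanning the
  barrier apex by default, so spacing trends are not diluted by the
  nucleosome-free region itself.
* **+1 nucleosome**: first dyad at offset ≥ 0; a yeast flag moves the
  window start to −50 bp.  The single-molecule pipeline keeps fragments
  of 140–180 bp, takes fragment midpoints as dyads (floor rounding), and
  summarizes per-gene means and population standard deviations; the
  pooled distribution of `x[n] − x[1]` (each molecule's +1 minus the
  gene's smallest +1) discriminates dropout artifacts — which concentrate
  at multiples of the repeat length — from genuine heterogeneity.

## Sequence affinity

`score_sequence()` implements a periodic-dinucleotide energy: every
dinucleotide in the footprint contributes a cosine of period 10.1 bp in
its offset from the candidate dyad, with AA/TT/TA/AT in phase (energy
lowered at crests) and GC in anti-phase.  The construction is exactly
strand-symmetric and translation-invariant on homopolymers; `N` bases
contribute nothing.  Because the absolute scale of such models is
convention-laden, all amplitudes are explicit configuration
(`affinity_params()`), and the profile is re-centered to a mean of
−42 kBT per footprint for use as a lattice `site_energy`.

## What the synthetic generators do and do not emulate

`generate_sequence()` plants a chosen dinucleotide at a fixed period into
an i.i.d. background — enough to exercise phasing detection, with no
attempt at genomic composition, isochores or repeats.
`generate_fragment_cohort()` builds single-molecule nucleosome arrays
with known per-gene +1 dispersion, repeat length, dropout and fragment
length jitter, plus optional out-of-range contaminants.  Tests passing on
these fixtures demonstrate that the pipeline recovers *planted* truth
under idealized noise; they say nothing about mappability, digestion
bias, or cell-type mixtures in real single-molecule data.

## Numerical choices and degenerate inputs

* Exponential waiting times and categorical event draws use a 64-bit
  Mersenne Twister inside the engine; replica seeds derive from the
  protocol's master seed through one documented `sample.int()` stream, so
  records are bit-for-bit reproducible.
* Incremental rate updates touch only terms affected by the last event;
  equality with from-scratch enumeration is asserted to 10⁻¹² in tests
  after hundreds of events, including ring-wrap moves.
* An all-rates-zero model is an absorbing state: the clock jumps to the
  horizon and the configuration is held for the remaining sample times.
* FFT convolutions zero the exact below-support range at every iteration
  (gaps below 147·k are impossible for k+1 rods), preventing round-off
  residue from leaking into number weights near capacity.
* Dyad-evaluated potentials make translation invariance exact; energies
  are pure functions of position and re-evaluation is bit-identical.

## Known limitations

* The effective attraction is a two-parameter piecewise-linear family
  calibrated at 1/5 scale; it reproduces interior-gap statistics and the
  qualitative profile phenomenology, but it is not a derivation of the
  full renormalized potential, and transferring the fit across very
  different densities or barrier shapes would require re-calibration.
* No sub-nucleosomal states, partial unwrapping, explicit transcription
  factors, or 3D structure; Pol II enters only through exchange rates.
* The phase-diagram scan runs one calibrated simulation per grid point
  and is correspondingly expensive; budget protocols accordingly.
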