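---
title: "Charge scaling and permeation analysis for potassium-channel simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charge scaling and permeation analysis for potassium-channel simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eccperm)
```

## Background

Fixed-charge force fields ignore electronic polarization: partial charges
interact through Coulomb's law in vacuum permittivity, although in reality
the electron clouds screen ionic interactions with a high-frequency
dielectric constant \(\varepsilon_{el} \approx 2\). The Electronic
Continuum Correction (ECC) folds this screening into the force field by
scaling the charges of ions and ionized groups by a factor
\(q = \sqrt{1/\varepsilon_{el}} \approx 0.7\). In potassium-channel
simulations this correction changes the picture qualitatively: scaled
charges let several K\(^+\) ions sit in adjacent selectivity-filter (SF)
sites, and single-channel conductances rise by an order of magnitude into
the experimentally observed range.

`eccperm` implements the methodological layer of such a study as a
reusable toolkit: the force-field preparation steps (charge scaling,
radius-corrected ion Lennard-Jones parameters, Born-model solvation
targets) and the trajectory analysis steps (SF occupancy coding,
permeation counting, conductance and I-V estimation, mechanism graphs
with MFPT rates and progressive lumping). Running the MD itself is out of
scope; synthetic generators with exact ground truth stand in for MD
output so every stage is testable offline.

## Charge scaling

Two force-field conventions are implemented.

**Group scaling** (`scale_group_charges()`), for force fields whose unit
charge is localized in one charge group: the partial charges of the group
carrying the formal charge (e.g. the \(-CH_2-CO_2\) group of aspartate,
net \(-1\,e\)) are multiplied by \(q\). Every other atom is untouched, so
a scaled residue's net charge is exactly \(q\) times its formal charge
and neutral systems stay neutral. The group membership table ships as an
editable CSV (`charged_groups.csv`, illustrative Charmm-style defaults
for ASP/GLU/LYS/ARG/HSP and monatomic ions); the function verifies each
group sums to an integer formal charge before scaling, so a membership
that does not match your force field fails loudly.

**Weighted scaling** (`scale_weighted_charges()`), for force fields that
spread the unit charge over the backbone: each atom's scaled charge is
the weighted average \(q \cdot q_i^{charged} + (1-q) \cdot
q_i^{neutral}\) over the ionized and neutral protonation states, which
again yields a residue net charge of exactly \(q \times\) formal. The two
schemes coincide whenever the two protonation states differ only inside
the charge group.

Scaling is exact in memory (full double precision; scaling by \(q\) then
\(1/q\) is an identity to 1e-9 e). Rounding happens only when a topology
is written: charges are printed to 6 decimals and the rounding residual
is redistributed in 1e-6 e steps within the charge group, so file-level
group sums equal the exact scaled sums. A read/write round trip of an
unmodified file is byte-identical.

## Radius-corrected ion parameters and Born-model targets

Scaling an ion's charge shrinks its first solvation shell unless the
Lennard-Jones radius is corrected. The correction workflow optimizes
sigma on a 0.05-grid of scaling factors (an MD grid search, out of scope
here) and interpolates linearly in between; `interpolate_ion_sigma()`
implements the interpolation, refusing extrapolation, and epsilon is
never modified. Anchor values are configuration input — the shipped
`sigma_anchors_example.csv` is synthetic and illustrative, not an
optimized parameter set.

The validation target for a scaled ion's solvation free energy comes from
the Born model. Writing the electronic part of solvation as a continuum
term

\[\Delta G_{ele} = -\frac{N_A z^2 e^2}{8\pi\varepsilon_0 r_0}(1 - q^2),\]

and approximating the full experimental solvation free energy by the Born
expression, the part the simulation should reproduce reduces to

\[\Delta G_{MD} = \Delta G_{Exp} \cdot q^2.\]

`born_scaled_solvation_target()` and `born_electronic_term()` implement
these with CODATA 2018 constants. Note the relation between the scaling
factor and the electronic dielectric constant is quadratic,
\(q^2 = 1/\varepsilon_{el}\): the \((1-q^2)\) factor above and the
\(\sqrt{1/2} \approx 0.7\) benchmark are only mutually consistent under
the quadratic form, so that is what the package uses throughout
(`scaling_factor_from_dielectric()`), even though the relation is
sometimes stated loosely as \(q = 1/\varepsilon_r\).

`eyring_barrier_difference()` converts rate ratios to barrier
differences, \(RT\ln(ratio)\): at 310 K, 10:1 corresponds to 1.4
kcal/mol and 2.5:1 to 0.6 kcal/mol — the scale on which force-field
selectivity errors should be judged.

## First solvation shell from RDFs

`compute_rdf()` computes the ion–water-oxygen radial distribution
function with minimum-image distances (orthorhombic or triclinic boxes)
and ideal-gas shell normalization, on a 0.002 nm grid by default.
`first_shell_radius()` finds the first peak and least-squares fits a
Gaussian \(A\exp(-(r-\mu)^2/2\sigma^2)\) to the 7 highest bins
contiguous with the peak maximum; \(\mu\) is the shell radius.

Numerical choices: the 7 points are required to be contiguous around the
first-peak maximum rather than the globally highest bins, because second
shells can rival first-shell shoulder bins; peak detection takes the
first strict local maximum above 20% of the profile maximum after the
excluded-volume region, a relative criterion so the fit is invariant to
uniform rescaling of g; ties break toward smaller r; the fit initializes
at \(\mu_0\) = argmax bin, \(\sigma_0\) = 2 bin widths, \(A_0\) = max g
and is solved by Levenberg–Marquardt least squares. Monotone profiles
and singular fits are rejected with diagnostics.

## Occupancy codes and site geometry

The filter is modeled as a cylinder around the pore axis sliced by the
five oxygen-layer planes into sites S1–S4, capped by S0 above (default
0.4 nm) and SCav below (default 0.4 nm), with a default lateral cutoff
of 0.25 nm. The exact cylinder dimensions are not prescribed by the
underlying protocol, so all three are explicit, overridable parameters
rather than inferred constants. Intervals are half-open
(lower-inclusive) so a particle on a plane belongs to exactly one site;
z increases toward the extracellular side, so outward permeation is +z.

Each frame maps to a 6-letter code over S0…SCav: `K` if a site holds an
ion, else `W` if it holds a water oxygen, else `0` (an ion takes priority
over a co-located water, since joint occupancy is not expressed in the
code alphabet; multiple ions in one site yield a single `K` with a
warning, with counts preserved in the per-ion site indices). Geometry can
be static or recomputed per frame from the filter-oxygen layer means, to
track filter breathing.

## Permeation counting and conductance

`detect_permeation_events()` uses a two-gate state machine: an outward
event requires touching the bath below the cavity and then reaching the
bath above S0 without returning below in between. The two gates give
hysteresis, so flicker across a single boundary can never double-count;
each full traversal yields exactly one event. Reversing time and the z
axis swaps outward and inward counts exactly.

Conversion to current uses the convention that one permeating ion
carries one full elementary charge regardless of its scaled partial
charge — the scaling is a mean-field model of electronic screening, not
a change in the transported physical charge. Conductance is current over
voltage; replicas aggregate as mean ± SEM (`aggregate_replicas()`), and
`iv_curve()` assembles per-voltage currents. Net signed counting
(outward − inward) is used where both directions occur; gross
directional counts remain available from the event table.
`state_populations()` reports occupancy-state fractions with percentile
bootstrap confidence intervals over frames (1000 resamples by default,
block length configurable for autocorrelated data).

`salt_concentration()` is the composition sanity check: cations per
water times 55.5 mol/L, reproducing the 0.8 mol/L of e.g. 160 K\(^+\)
per 11,134 waters.

## Mechanism graphs

The discretized trajectory defines transition statistics for every
ordered state pair: direct transition counts, net flux (forward minus
backward counts), and the rate defined as the inverse mean first passage
time — the mean, over entries into A, of the time to the first
subsequent visit of B, with passages cut off by the trajectory end
censored. Replicas pool passage times before averaging (never averaging
per-replica rates), and trajectory boundaries are never spliced.

`lump_graph()` simplifies the graph progressively: while the fastest
inter-state rate exceeds the cutoff, that pair is merged, the
trajectory is relabeled, and all rates are recomputed on the relabeled
discrete trajectory (not by algebraic graph contraction — rates are
trajectory-defined, so they must be re-measured). Lumped nodes are named
by joining member codes with `+` in lexicographic order; their
populations are exact sums of member populations, and decreasing the
cutoff never undoes a merge.

`rate_limiting_step()` operationalizes "the slow step carrying the
flux": among node pairs whose |net flux| is at least a threshold
fraction (default 0.5) of the total permeation flux, it returns the pair
with the smallest forward rate. If no pair qualifies, the maximal-flux
pair is returned with a warning flag rather than an error. Node colors
and classes count `K` letters over all six positions S0–SCav by default
(configurable to the S1–S4 window).

## Synthetic generators and what they do (not) show

`simulate_ctmc()` is an exact Gillespie simulator over arbitrary state
labels: exponential waiting times, categorical jumps, uniform-stride
observation, with the continuous-time jump log retained as ground truth.
`simulate_channel()` emulates direct knock-on permeation at coordinate
level: ions hop single-file between the six site centers and two baths
with voltage-biased rates under a strict one-ion-per-site exclusion
rule; waters fill ion-free sites with probability 0.9 per frame; emitted
coordinates sit at site centers plus jitter bounded at 25% of the
smallest site half-width, so site assignment is unambiguous and
discretization reproduces the generator's state sequence at every frame.

Default generator conditions were chosen once to mimic the qualitative
permeation picture of ECC simulations — predominance of 3-ion and 4-ion
codes alternating under outward bias (hop rates 2/0.2 ns\(^{-1}\)
outward/inward, entries 2/0.2 ns\(^{-1}\), four ions initially at
S1/S2/S3/SCav). Bath entry is a property of the bath (one candidate ion
at a time), so the entry rate does not scale with the staged roster;
ions that complete a traversal rest in the destination bath, and
recycling is represented by pre-staged ions, so no per-ion track ever
teleports. Event ground truth is recorded at observation resolution with
the same two-gate convention the detector uses: a bath excursion briefer
than the stride is consistently absent from both the truth and anything
recoverable from the frames (the continuous-time crossing log is kept
separately).

What passing these tests shows: the geometry, coding, counting, MFPT and
lumping machinery is exact on data whose truth is known. What it does
not show: anything about force-field accuracy, about real SF geometries
(no lateral ion escape, no water co-permeation, no filter distortion),
or about the statistical difficulty of real MD data (the generators'
jitter is bounded by construction; real trajectories require the
per-frame geometry mode and produce boundary flicker that the two-gate
counter is designed to absorb).

## Problem sizes and statistical design of the test suite

The suite validates stochastic properties at sizes chosen for tight
statistics: MFPT against the analytic 1/k uses ten 1-μs two-state chains
observed at 0.02 ns; population recovery uses 2-μs three-state chains
observed at 1 ns — a stride comparable to the chain's relaxation time,
because frame-level bootstrap intervals are only calibrated for weakly
correlated frames; round-trip channel recoveries use 40–200 ns runs with
60–200 staged ions. Exhaustive oracle comparisons (MFPT scan, RDF double
loop) run on trajectories of a few hundred frames and up to six states,
where the O(n²) oracles are instant.

## Known limitations

- Topology I/O covers the `[ atoms ]` block dialect; other sections pass
  through verbatim but are not interpreted.
- Binary MD trajectory formats are not read directly; the columnar
  fixture CSV and multi-model PDB (via bio3d) are the supported inputs.
- The weighted scaling scheme needs per-state charge sets and is exposed
  at function level, not through the file-level CLI.
- Rates are MFPT-inverse by definition; no Markov-state-model estimation
  (no lag-time selection, no spectral analysis) is attempted.
- The lumping cutoff is applied to the rate itself; where a published
  figure legend mentions a "product" exceeding a cutoff without defining
  it, this package documents and uses the rate.
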