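---
title: "Quantifying ABC-transporter flexibility: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ABC-transporter flexibility: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abcflex)
```

# Scope

P-glycoprotein and its ABC-exporter relatives are believed to be unusually
flexible in the inward-facing state: the two nucleotide-binding domains
(NBDs) sample separations spanning tens of Angstrom, and the flexibility is
thought to originate from kinking/unwinding hinges in the transmembrane
helices, enriched in glycine and proline. `abcflex` implements the
quantitative layer needed to test such claims on structural ensembles and
pulsed-EPR data:

1. inter-domain center-of-mass (CoM) distance traces and 0.1 Å population
   histograms over a multi-frame structure ensemble;
2. Kabsch superposition, per-residue r.m.s.f. and the theoretical B-factor
   conversion θ = (8π²/3)·(r.m.s.f.)²;
3. backbone i→i+4 hydrogen-bond occupancy and helical-defect calling;
4. simulation and Tikhonov inversion of 4-pulse DEER dipolar signals;
5. Gly/Pro composition statistics over annotated TMD alignment regions;
6. seeded synthetic generators for each input type, with ground-truth
   manifests, so the whole pipeline is testable without external data.

# Ensemble geometry

## Center-of-mass distances and histograms

The per-frame readout is the Euclidean distance between the centers of mass
of two atom selections (typically the two NBDs, or a Walker A motif paired
with the opposing LSGGQ motif). Published analyses rarely state whether CoM
used atomic masses or an unweighted centroid, so both are implemented
(`weighting = "mass"` is the default; for CA-only selections the two
coincide).

Distances pool across replicate trajectories into a normalized histogram
with a default bin width of 0.1 Å. Numerical conventions: bins are anchored
at integer multiples of the width (`floor(d / w)`), a sample falling
exactly on an edge goes to the upper bin, probability mass sums to 1 within
1e-12 and the reported mean is the pooled sample mean. `discard_first`
drops leading equilibration frames; `ns_to_frames()` converts a time span
when frame times are present (trajectory studies commonly discard the
first ~10 ns).

## Superposition, r.m.s.f. and theoretical B-factors

`superpose()` performs a rigid-body (Kabsch, SVD-based, no scaling) fit of
each frame onto a reference. Because published work rarely states the
fitting protocol, the default reference is the ensemble mean structure
computed iteratively (fit onto frame 1, recompute the mean, refit; two
refinement passes), with frame-k and external-coordinate references
available. Collinear fit sets leave the rotation undetermined and are
rejected. `rmsf()` is the 3-D fluctuation about the time-mean position;
`rmsf_to_bfactor()` applies the isotropic harmonic conversion
θ = (8π²/3)·(r.m.s.f.)², in Å², exactly and elementwise.

## Contacts

`contact_count_trace()` counts probe atoms within a cutoff of any site
atom per frame — e.g. acyl-chain carbons of a lipid against lumen-lining
residues when following lipid protrusion through a TMD portal. The default
cutoff is 4.0 Å (heavy-atom contact convention; published observations of
this kind typically state no cutoff).

# Helical defects

The (i)C=O···H–N(i+4) backbone hydrogen bond defines α-helical
continuity; a bond that is absent in a large fraction of frames marks a
kink or unwinding hinge. Published defect maps state the persistence rule
(absent in >30% of simulation time) but not the geometric criterion, so
the criterion is explicit and configurable: d(N,O) ≤ 3.5 Å (inclusive
boundary), plus an N–H···O angle ≥ 120° when amide hydrogens are present.
Both thresholds are echoed into every output file.

`call_defects()` flags a pair when the absence fraction strictly exceeds
`threshold_absent` (default 0.30): occupancy exactly 0.70 is *not* a
defect. The sentence "fails to persist for more than 30% of the time" also
admits the reading "persists in fewer than 30% of frames"; that alternative
is available as `strict_persistence = TRUE` rather than silently chosen.
Occupancies are frame-count ratios, so the comparison uses a 1e-9 epsilon
to keep e.g. `1 - 0.70 > 0.30` from being decided by floating-point
representation. Missing backbone atoms skip a pair with a warning rather
than aborting the map.

# DEER simulation and inversion

## Forward model

The isotropic powder-averaged dipolar kernel is

K(t, r) = ∫₀¹ cos[(3x² − 1) ω(r) t] dx,  ω(r) = 2π D / r³,

with D = 52.04 MHz·nm³ for a nitroxide pair (a field standard, overridable).
The default evaluation uses the Fresnel-integral closed form; a fixed-order
Gauss–Legendre quadrature route (default order 1024, which resolves the
fastest oscillation on the default grid, r = 1.5 nm at t = 4 µs) is kept as
an independent cross-check — the two agree to better than 1e-6 everywhere.
The simulated signal is

V(t) = [1 − λ + λ·(K p Δr)] · exp(−k t^{d/3}) + ε,

with modulation depth λ, stretched-exponential intermolecular background
(d = 3 for homogeneous solution) and seeded Gaussian noise; every
stochastic operation requires an explicit seed and leaves the global RNG
untouched.

## Background correction and inversion

`background_correct()` fits log V linearly against t^{d/3} over the tail
window (default: the last 40% of the trace, where the dipolar oscillation
of a well-sized measurement has decayed), divides the decay out, and reads
the modulation depth from the fitted asymptote. The window start and
dimensionality are parameters; a window with fewer than 10 points or
non-positive amplitudes is an error.

`tikhonov_invert()` solves

min_{p ≥ 0}  ‖K p Δr − s‖² + α²‖L₂ p‖²

with L₂ the second-difference operator with reflective boundary rows. The
stacked least-squares system is compacted through its normal equations —
chol(AᵀA) = R and min‖Rx − R⁻ᵀAᵀb‖ has the same minimizer — and solved by
Lawson–Hanson NNLS (`pracma::lsqnonneg`), which keeps the constrained
solve fast at the default 256-point grid. By default the modulation depth
is estimated *jointly* with the distribution through an unpenalized
constant offset column (since K(0, r) = 1 and V(0) = 1, the offset is
1 − λ and λ = Σp̂Δr before normalization); this is markedly more robust
than dividing by a tail-window depth estimate. Passing a fixed `lambda`
instead solves the literal two-step problem.

α defaults to the L-curve corner: maximum finite-difference curvature of
(log residual, log penalty) over a log-spaced grid (default 12 points,
1e-3 to 10); a degenerate curve falls back to the mid-grid α with a
warning.

## Summary statistics and artifact suppression

Non-negative inversions of noisy traces often show small spurious peaks
disconnected from the main distribution. These distort grid-wide moments
badly while being visually obvious artifacts — at a signal-to-noise ratio
of 30 (defined here as λ/σ) a disconnected component carrying ~4% of the
mass at 2 nm shifts the mean of a 4 nm distribution by ~0.1 nm.
`distribution_stats()` therefore prunes connected components holding less
than 10% of the total mass (renormalizing the rest) before computing the
mean, mode, FWHM and 5%-of-maximum support width; `prune_minor = 0`
disables this. Across 40 seeded replicates of the single-Gaussian
round trip (mean 4.0 nm, sd 0.3 nm, SNR 30) pruning reduces the maximum
mean-recovery error from ~0.26 nm to ~0.035 nm. The pruning threshold is
uniform, never tuned per trace.

## Choosing the evolution window

The r grid defaults to 1.5–8 nm (256 points), spanning the 28–60 Å range
typical of inter-NBD label pairs. Recoverability depends on the trace
length relative to the dipolar period (3.7 µs at 5.8 nm): a 4 µs trace
comfortably resolves a 4 nm component but cannot separate a broad 5.8 nm
component from the background — the tail fit absorbs the signal. Matching
the window to the expected distance (e.g. 8 µs for a 5.8 nm, 2 nm-FWHM
component) restores recovery of both the mean and the width. The synthetic
generator default (4 µs, 250 points) is sized for the 4 nm test case.

# Sequence composition

`count_glypro()` counts G and P among non-gap characters of an alignment
row restricted to a 0-based half-open column span; ambiguity codes
(B, Z, X, …) count toward residue totals but never as Gly/Pro. TMD spans
are consumed as user-supplied column intervals (e.g. from Pfam match
states): whether a region means one half-transporter TMD or the full pair
is a dataset question the span abstraction leaves to the user.
`compare_groups()` reports differences of mean per-sequence counts with
seeded percentile bootstrap confidence intervals (default 10,000
resamples). No claims are made about any particular database snapshot;
the comparison machinery is the deliverable.

# Synthetic generators: what they emulate, and what not

* `make_hinged_trajectory()` — two rigid pseudo-domains on arms meeting at
  a hinge, with the hinge angle driven so the inter-domain CoM separation
  follows base + amplitude·sin(2πf/period) (defaults 40 ± 20 Å over 100
  frames): separation arises from hinge bending, not translation,
  mirroring — at toy-geometry level — the idea that NBD motion originates
  from helical hinges. Ideal helical linkers ride the arms; designated
  (i, i+4) pairs have their carbonyl O displaced 3 Å directly away from
  the partner N in exactly `round(fraction · F)` seeded frames, so planted
  break fractions are recovered exactly. Thermal jitter (default σ =
  0.5 Å per coordinate) applies to domain atoms only, leaving the planted
  hydrogen-bond geometry noiseless; domain-CoM noise then propagates as
  ~σ√(2/n) per frame. Not emulated: force-field physics, membranes,
  anisotropic or correlated fluctuations.
* `make_ideal_helix()` — backbone N, CA, C, O (optionally H) placed on a
  helical wheel whose per-atom radial/angular/axial offsets were
  calibrated on a φ = −57°, ψ = −47° helix (rise 1.562 Å, twist 99.67°,
  CA radius 2.259 Å); every (i, i+4) pair satisfies the default H-bond
  criterion with d(N,O) ≈ 3.11 Å.
* `make_synthetic_deer()` — Gaussian-mixture truth on the default grid,
  signal through the package's own forward model. The default single
  component (5.8 nm, 2.0 nm FWHM) emulates a broad inter-NBD label
  distribution. Not emulated: orientation selection, excluded volume,
  spin-label rotamers.
* `make_sequence_set()` — i.i.d. residues with controlled G/P frequencies;
  real alignments have phylogenetic correlation and gaps, so passing tests
  demonstrate counting and inference machinery, not biological effect
  sizes.

Every generator embeds its seed and planted truth in a manifest consumed
directly by the test suite.

Two additional constructors, `synthetic_label_site_structure()` and
`synthetic_closed_nbd_dimer()`, are *stand-ins* for crystal-structure
reference objects: their construction embeds the published geometry (a
48 Å label-site Cβ separation; a 26.0–26.5 Å protomer CoM separation of a
closed NBD dimer), so tests against them exercise the I/O, selection and
distance machinery rather than independently verifying crystallographic
values. With the corresponding real PDB entries on disk, the same
`read_pdb_ensemble()` + `pair_distance()`/`com_distance_trace()` calls
perform the genuine check.

# Pipeline

`run_pipeline()` executes the stages named in a single config (R list or
YAML): trajectory input or synthesis, fail-fast selection resolution,
distances/histograms, r.m.s.f. + B-factors, hydrogen-bond defects,
contacts, DEER inversion and Gly/Pro summaries, writing per-stage
CSV/TSV tables plus a `summary.json` carrying a canonical-JSON config
fingerprint. Given identical inputs, config and seed, outputs are
byte-identical.

# Problem sizes and limitations

The test suite and the acceptance script run at deliberately compact
sizes — ensembles of 10–100 frames and a few hundred atoms, DEER traces of
250–400 points on 128- or 256-point distance grids, 20-replicate recovery
studies, sequence sets of 500×200 — chosen so the full suite completes in
a couple of minutes while every statistical check retains adequate power.

Known limitations: PDB numbering follows the file's author numbering and
mmCIF is not parsed; the hydrogen-bond criterion is a geometric
convention, not a recomputation of any particular secondary-structure
assignment tool; DEER inversion assumes an isotropic powder average and a
single stretched-exponential background; helical-defect and distance
analyses assume the ensemble's atom ordering is constant across frames.
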