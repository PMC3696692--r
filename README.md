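# abcflex

Quantitative analysis of conformational flexibility in ABC transporters
(P-glycoprotein and its relatives), combining structural-ensemble geometry
with pulsed-EPR distance analysis.

ABC exporters couple ATP binding/hydrolysis in two nucleotide-binding
domains (NBDs) to alternating access of two transmembrane domains (TMDs).
In the inward-facing state the NBDs can sample separations spanning tens
of Ångström, and this flexibility is thought to originate from
kinking/unwinding hinges in the transmembrane helices, enriched in glycine
and proline. `abcflex` provides the analysis layer for testing such claims:

* **Ensemble geometry** — multi-MODEL PDB ensembles, an atom-selection
  grammar (`chain A and resid 423-431 and name CA`), center-of-mass
  distance traces between domains, pooled 0.1 Å population histograms,
  Kabsch superposition, per-residue r.m.s.f. and the theoretical
  B-factor conversion θ = (8π²/3)·(r.m.s.f.)², RMSD against template
  coordinates, and portal contact counts.
* **Helical defects** — backbone (i)C=O···H–N(i+4) hydrogen-bond occupancy
  over an ensemble, with a defect called when the bond is absent in
  strictly more than 30% of frames (threshold and geometric criterion
  configurable and echoed into outputs).
* **DEER** — 4-pulse double electron-electron resonance: the powder-averaged
  dipolar kernel (Fresnel closed form, Gauss–Legendre cross-check,
  D = 52.04 MHz·nm³), forward simulation with modulation depth and
  stretched-exponential background, background correction, and Tikhonov
  inversion to P(r) by non-negative least squares with second-difference
  regularization and L-curve selection of α.
* **Sequence composition** — Gly/Pro content of annotated TMD regions of
  alignments (FASTA/Stockholm), with seeded bootstrap group comparisons.
* **Synthetic generators** — ground-truthed hinged trajectories, ideal
  α-helices, DEER traces and sequence sets, so the entire pipeline is
  testable offline; every generator emits a manifest with its seed and
  planted truth.

See `vignettes/flexibility-analysis.Rmd` for the methods and the design
decisions behind the defaults.

## Worked example

Generate a hinged two-domain trajectory with a planted ±20 Å separation
signal and two planted hydrogen-bond breaks, then analyze it:

```r
library(abcflex)

gen <- make_hinged_trajectory(hinged_config(
  n_frames = 100, seed = 42,
  broken_pairs = data.frame(resid = c(3, 7), fraction = c(0.5, 0.1))))
ens <- gen$ensemble

nbd1 <- resolve_selection(ens, "chain A", "NBD1")
nbd2 <- resolve_selection(ens, "chain B", "NBD2")
tr <- com_distance_trace(ens, nbd1, nbd2)
print(tr)
#> DistanceTrace NBD1--NBD2: 100 frames, mean 40.00 A, range [19.98, 60.08] A

h <- pooled_histogram(tr, bin_width = 0.1)
print(h)
#> DistanceHistogram: 100 samples in [19.9, 60.1] A, bin 0.1 A, mean 40.00 A
histogram_support_width(h)
#> [1] 40.2
```

The recovered range brackets the planted 40 ± 20 Å sinusoid. Defect
calling flags exactly the pair broken in >30% of frames (residue 3 at
50%), not the 10% pair:

```r
def <- call_defects(occupancy_map(ens, "L", 1:11))
def[def$defect, c("chain", "resid", "occupancy", "defect")]
#>   chain resid occupancy defect
#> 3     L     3       0.5   TRUE
```

A DEER round trip at signal-to-noise 30 — simulate from a Gaussian P(r)
centered at 4.0 nm, correct the background, pick α on the L-curve and
invert:

```r
sim <- make_synthetic_deer(deer_sim_config(
  components = data.frame(mean = 4.0, sd = 0.3, weight = 1),
  lambda = 0.3, noise_sigma = 0.01, seed = 7))
bc <- background_correct(sim$trace)
g <- r_grid()
alpha <- select_alpha_lcurve(bc$form_factor, g)
fit <- tikhonov_invert(bc$form_factor, g, as.numeric(alpha))
distribution_stats(fit$p_hat)[c("mean", "fwhm")]
#> $mean
#> [1] 4.001106
#> $fwhm
#> [1] 0.8133398
```

The recovered mean is within 0.002 nm of the truth; the FWHM (0.81 nm vs
the true 0.71 nm) shows the expected regularization broadening.

For orchestrated runs, `run_pipeline()` takes a single config (R list or
YAML) naming the stages, selections and parameters, and writes per-stage
tables plus a `summary.json` with a config fingerprint; reruns with the
same seed are byte-identical.

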