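---
title: "Modelling P450 monolayer formation on carbon nanotubes and calibrating the voltammetric drug response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling P450 monolayer formation on carbon nanotubes and calibrating the voltammetric drug response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypcnt)
```

`cypcnt` models two halves of a cytochrome-P450/carbon-nanotube drug
biosensor at desk scale: (i) how the enzyme forms a self-assembled monolayer
on the nanotube walls, and (ii) how the resulting electrode's
cyclic-voltammetry response calibrates against drug concentration. This
vignette is the package's account of the science behind both halves: the
models, their assumptions, the tunable parameters, and what the synthetic
data can and cannot show.

## 1. Adsorption energetics

Protein--surface complex formation is described by the free-energy
decomposition

$$\Delta G = \Delta H_\Phi + \Delta H_{EL}
  - T(\Delta S_{CF} + \Delta S_{TR} + \Delta S_{ID}),$$

with a hydrophobic enthalpy, a Van der Waals term, and conformational,
translational/rotational and water-stabilisation entropies. For adsorption
onto the strongly hydrophobic nanotube walls the hydrophobic term dominates,
and it is proportional to the buried contact area,

$$\Delta H_\Phi = \alpha\, A_\mathrm{contact},
  \qquad \alpha = -104.5\ \mathrm{J\,mol^{-1}\,\AA^{-2}},$$

the coefficient measured on antibody--antigen complexes (104.5 J/mol per
buried square Angstrom). Note the units: some write-ups quote this
coefficient per nm^2^, but only the per-Å^2^ reading is consistent with the
landmark values it must reproduce (272 Å^2^ → −28 kJ/mol, 378 Å^2^ →
−40 kJ/mol, 150 Å^2^ → −16 kJ/mol at two significant figures), so
`hydrophobic_model()` defaults to −104.5 J/(mol·Å^2^). At 690 Å^2^ — the
upper end of typical antigen--antibody contacts — the coefficient gives
−72.1 kJ/mol; a commonly quoted −74 kJ/mol for that area is not consistent
with this α and is not reproduced here.

The remaining terms of the decomposition are not quantified by any input we
model; `energy_terms()` carries them (defaulting to zero) so the full
expression is representable and configurable, and `gibbs_free_energy()`
reduces to the hydrophobic enthalpy when they vanish.

## 2. Geometry: a prism on a cylinder

Crystallographically, P450 is approximated as a triangular prism of
4.5--5 nm × 5--6.5 nm × 3.5--4.5 nm (`protein_prism()`), adsorbing onto a
cylinder of 10 nm diameter and 1--2 µm length (`nanotube()`). Five
attachment modes are enumerated (`make_orientation_set()`): the preferred
lateral (largest) face down, the triangular face down, long-edge, short-edge
and corner contacts. Their radial extents — how far the molecule protrudes
above the wall — are respectively the thickness, the long edge, the short
base edge, and (for the edge/corner modes) the long edge.

A flat face resting on a cylinder of radius $r$ touches along a line; the
gap grows as $g(x) = r - \sqrt{r^2 - x^2}$ with transverse offset $x$.
Counting as "in contact" the strip where the gap is below a cutoff $c$
gives, in the small-gap regime, a strip width $w = 2\sqrt{2rc}$ and a
contact area $w \cdot \ell$ for a face of length $\ell$ along the tube axis
(`contact_strip_area()`). The effective contact lengths are the full face
length for the two flat-face modes (long edge and thickness respectively)
and are halved for edge contacts (quartered, via thickness/2, for the corner
mode) to reflect the adjoining-face tilt; this parameterisation is a
modelling choice, since the orientations are pictured but not dimensioned in
the source material.

Two numerical choices matter here:

* **Contact cutoff, default 0.009 nm.** The estimated P450--nanotube contact
  range is 272--378 Å^2^, but no construction from the prism dimensions to
  that range is documented. We calibrate the single free constant $c$ once
  so that the lateral-face contact of the midpoint prism
  (4.75 × 5.75 × 4.0 nm) on a 10 nm tube lands inside that range: with
  $c = 0.009$ nm, $w = 0.6$ nm and $A = 345$ Å^2^. The calibration is
  geometric, made before any downstream statistic, and not revisited.
* **Unrolled-cylinder footprints.** Footprints are rectangles on the
  unrolled surface (axial × arc, arc periodic with period $\pi d$);
  curvature distortion is neglected because a ~5 nm footprint is small
  against the ~31.4 nm circumference. Overlap with azimuthal wrap-around is
  exact for rectangles narrower than the period (`rects_overlap()`).

## 3. Monolayer formation by random sequential adsorption

Self-assembled-monolayer formation is modelled as random sequential
adsorption (`run_rsa()`): candidate positions are uniform on the unrolled
surface, the orientation is drawn with probability proportional to its
hydrophobic contact area (the stated attachment rule; a Boltzmann weighting
$\propto e^{-\Delta G/RT}$ is available in `orientation_probabilities()` but
is not the default), and a candidate is accepted only if its footprint
overlaps no previously adsorbed molecule. Nothing desorbs or diffuses.

Saturation ("jamming") is asserted but never operationalised in the source
material; we stop after 10,000 consecutive rejections, deep in the jamming
regime for these sizes. Each adsorbed molecule draws its own prism
dimensions uniformly within the crystallographic ranges, which reproduces
the few-nm spread of measured coated diameters rather than a single
deterministic value. Axial boundaries are hard; the arc coordinate wraps.
Reproducibility is by a single seeded generator per tube, per-tube seeds
derived as `seed + tube index`.

The SEM-style measurement (`projected_diameter_profile()`) emulates what a
micrograph shows: a projected outline. At each sampled axial position the
apparent width is the bare diameter plus the largest radial extent among
covering proteins on each silhouette side (footprint-centre arc position
decides the side), i.e. one protein layer per side — which is why a ~5 nm
monolayer reads as a ~10 nm diameter increase.

With the defaults (50 tubes of 10 × 1000 nm, ~900 molecules per tube,
`simulate_ensemble()`), the ensemble gives a coated diameter near 20.8 nm
(against 20 ± 4 nm measured), a diameter increase near 10.8 nm (against
10 ± 4 nm), a mean layer thickness near 5.2 nm (inside the 3--6 nm band)
and a jamming coverage near 0.58 — consistent with the ~0.55 jamming
density of aligned-rectangle RSA. One emergent feature worth knowing: at
jamming the *realised* orientation mix shifts toward small-footprint modes
(triangular-face, corner) relative to the attempt probabilities, because
large lateral footprints are rejected more often late in the packing. The
mean thickness therefore sits above the lateral-face thickness alone.

Problem sizes were chosen so the full ensemble is a few seconds of
computation: 50 tubes of 1000 nm at jamming is ample for ±0.1 nm stability
of the ensemble mean (two independent 10-tube runs differ by well under
1 nm), and larger runs only polish digits the comparison bands do not
resolve.

## 4. Synthetic voltammograms

No raw potentiostat data are deposited anywhere we can draw on, so the
calibration pipeline is exercised against a synthetic generator
(`generate_voltammogram()`) with the statistical structure the analysis
assumes:

* triangular sweep −600 → +300 → −600 mV at 20 mV/s, 1 mV step (sampling
  density is otherwise unstated);
* a capacitive background ± `capacitance_scale` × scan rate (sign by sweep
  direction — the hysteresis envelope) plus a linear ohmic baseline;
* Gaussian faradaic peaks in potential, each on its own sweep segment.
  Gaussian shape keeps amplitude and location analytically known, so the
  generator doubles as ground truth for extraction tests. The default
  σ = 15 mV (FWHM ≈ 35 mV) keeps the cathodic regions at −330 and −450 mV
  and the nanotube oxygen-moiety peak at −200 mV separable;
* i.i.d. Gaussian sample noise — the simplest model consistent with a
  3σ-based detection limit;
* amplitudes linear in concentration:
  `per-area sensitivity × 12.56 mm² × concentration + blank`.

The per-area sensitivities, pharmacological ranges and monitored peaks ship
as presets (`drug_presets()`): cyclophosphamide 2B6 1.0|0.3, 3A4 0.6|0.3;
ifosfamide 2B6 1.2|0.1, 3A4 1.6|0.4; ftorafur 1A2 8.8|3.9; etoposide on the
plain nanotube electrode 73.7|9.1 nA/(µM·mm²) (PBS|serum). Serum is
emulated *only* as this preset sensitivity reduction — plasma-protein drug
binding is the accepted cause, but no binding kinetics are modelled.
Absolute background and blank magnitudes are only ever shown graphically in
the experimental record, so `capacitance_scale = 25 nA/(mV/s)`,
`baseline_slope = 0.2 nA/mV`, `noise_sd = 5 nA` and `blank_nA = 50` are free
parameters of the emulation, fixed once at plausible magnitudes. Oxidation
features quoted at +450 mV (and the +350 mV reduction) lie beyond the
+300 mV sweep limit and are not generated.

Hetero-activation — a second drug raising the enzyme's activity toward the
first — is modelled as a linear sensitivity multiplier
(`effective_sensitivity()`): $S(m) = S_0 (1 + \gamma m)$ for modulator
concentration $m$. The observed behaviour is a monotone increase with no
stated functional form; linearity is the minimal choice. The worked
analyses use γ = 0.005 µM⁻¹ (a 50% sensitivity gain at 100 µM etoposide, in
the visually reported range) and γ = 0 for the no-interaction pairing.

## 5. Calibration analysis

`extract_peak_current()` implements the peak-picking convention: a straight
baseline fitted through the two margins flanking the search window (just
outside it, default 45 mV half-window and 20 mV margins for the monitored
peaks — placed so the neighbouring peak regions stay out of both), and the
peak is the extremal signed deviation from that baseline inside the window.
The extremum is *located* on a 7-sample running mean so a single noise spike
cannot claim the peak, but the *reported* current is the raw deviation at
that location — noiseless peaks are therefore recovered exactly (to the
sub-percent tail-overlap level), and noisy blanks inherit the injected
noise sd rather than an extreme-value-inflated one. The exact peak-current
procedure used experimentally is cited to an unavailable reference, so this
is a documented default, not a reconstruction.

`fit_calibration()` is ordinary least squares of |peak current| on
concentration (absolute value so cathodic and anodic series share one
convention); the slope is the sensitivity in nA/µM and divides by the
12.56 mm² electrode area for per-area units. The fitting range equals the
drug's pharmacological range — both sensitivity and detection limit are
defined "inside the linear range", which is never defined independently, so
the pharmacological range stands in for it. `detection_limit()` is
3·sd(blank peak currents)/slope. `analyze_panel()` chains
extract → fit → LOD over a panel and tabulates per drug/isoform/matrix.
Cytochrome electrodes are monitored at the −330 mV cathodic peak; the
companion −450 mV region is generated and extractable but reported
separately; the nanotube/etoposide electrode is monitored at +220 mV.

`analyze_drug_pair()` fits one sensitivity per modulator level and
regresses sensitivity on modulator concentration. `monotone_increase`
requires every successive sensitivity to rise; `overlap` holds when the
activation slope is statistically indistinguishable from zero — a
two-sided t-test on the regression coefficient at level 0.05, chosen
because the no-interaction claim is otherwise only visual. The test needs
at least three modulator levels; with two, the flag is `NA`. By
construction this test has a 5% false-activation rate under γ = 0, so
roughly one synthetic replicate in twenty will (correctly, statistically)
fail to declare overlap.

## 6. What the synthetic data do and do not show

The generator emulates the *assumed statistical structure* of the
experiment: linear response, Gaussian peaks at the reported potentials,
additive noise, preset sensitivities. Tests passing against it demonstrate
that the pipeline recovers what the generator encodes — slopes within 5% at
1% noise, LODs scaling linearly in blank noise and inversely in slope,
hetero-activation flags behaving as designed. They do **not** validate the
electrochemistry of real electrodes: peak shapes, drifting baselines,
correlated noise, fouling, serum matrix effects beyond a scalar sensitivity
loss, and multi-layer deposition currents are all outside the model.
Likewise the adsorption model reproduces coating *statistics* (diameter,
thickness, their spread), not molecular detail: no atomistic structure, no
per-face hydrophobicity map (those site percentages are not numerically
available), no desorption, and no tube bundling.

## 7. Degenerate inputs and edge behaviour

Invalid geometry (non-positive lengths, thickness exceeding the base edge,
cutoff ≤ 0 or beyond the radius), empty orientation lists, non-positive
contact areas, peaks outside the sweep, unknown presets or matrices, and
degenerate calibration designs all raise classed errors early. A tube
shorter than a footprint refuses to run; a tube barely longer than one
footprint adsorbs at most what fits. Zero-width contact (cutoff 0) gives
zero area; an empty adsorption state has a bare-tube diameter profile and
no thickness statistics (error). Ties in peak extraction resolve to the
first extremum; touching footprints do not count as overlap (open
intervals), consistent between the fast path and the translate oracle.
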