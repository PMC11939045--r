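---
title: "Models and methods behind rcaflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rcaflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rcaflow` is a simulation and processing toolchain for row-column-addressed
(RCA) ultrasound sensors aimed at 3D ultrafast Doppler imaging of the
peripheral microvasculature. This vignette is the package's account of its
models: what is simulated, which knobs matter, which design choices were
genuinely open, and what the synthetic studies do and do not demonstrate
about real acquisitions.

## Geometry and conventions

An RCA probe addresses an N x N transducer grid through N row and N column
electrodes. Rows are strips running along x, indexed by their y position;
columns run along y, indexed by x. Transmitting on one set of strips and
receiving on the orthogonal set yields cylindrical focusing in two
orthogonal planes and hence full 3D focusing after compounding, at N + N
instead of N^2 channels. The default `array_spec()` is the characterised
sensor: 64 + 64 elements at 150 um pitch (9.6 mm aperture). Coordinates
are metres, origin at the array centre, z into the medium; flow towards
the array is positive in every Doppler convention of the package.

## Transmit schemes

`build_scheme()` constructs the four emission plans:

* **SA** - one single-element cylindrical-wave transmit per element;
* **HSA** - all elements fire every event with +-1 polarities taken from
  the rows of the Sylvester Hadamard matrix; `hadamard_decode()` restores
  the single-element data with the full `sqrt(order)` amplitude SNR gain
  (exactly, in the linear model);
* **SPW** - steered plane waves on one array (delay law
  `u sin(theta) / c`, min-shifted so the first element fires at t = 0);
* **OPW** - the same angle grid emitted first by the rows then by the
  columns; both orientations are beamformed and coherently averaged.

The compound volume rate is `prf / n_events`: 64 orthogonal plane waves at
a 20 kHz PRF give 312.5 volumes/s; 16 give 1250 volumes/s. Angle grids
follow the phantom-study table (1 degree steps about zero); the 8+8 and
SPW16 grids, which that table does not print, continue the same pattern
(-3.5:1:3.5 and -7.5:1:7.5).

## The time-of-flight simulator

`simulate_ensemble()` replaces a full diffraction simulator with linear
time-of-flight superposition: every scatterer re-emits a delayed copy of
the effective pulse, with the transmit distance evaluated in the steering
plane and the receive distance in the orthogonal plane (strip elements are
delay-invariant along their long axis). Two fidelity points matter:

* **Discrete-element transmit (default).** A steered "plane wave" is
  synthesised as 64 delayed cylindrical wavelets rather than an ideal
  infinite plane. The finite aperture's edge behaviour is what limits
  plane-wave image quality at low angle counts, so the ideal-plane model
  (`tx_model = "plane"`, ~64x faster) is reserved for long Doppler
  ensembles where only the slow-time dynamics matter. SA/HSA are identical
  under both models, and HSA ensembles are synthesised by Hadamard-encoding
  simulated SA events, which is algebraically exact in a linear medium.
* **Transducer bandwidth.** The excitation (two-cycle Hann burst at
  9.02 MHz) is convolved with a Gaussian impulse response representing the
  measured 73% two-way fractional bandwidth. This sets the axial
  resolution and determines whether angle-comb side lobes survive
  broadband smearing; disable with `bandwidth_frac = NULL`.

Omissions, by design: no 1/r spreading (all reported metrics are
relative), no attenuation or dispersion, no nonlinearity, no multiple
scattering, no elastic structures (bone), no element cross-talk, and no
transmit-voltage asymmetry - the mechanism generally held responsible
for HSA's penalty in hardware - so HSA here is an upper bound on its
real performance.

Doppler phase is *emergent*: scatterers are advanced between compound
frames by `advance_phantom()` (modular advection along each vessel with
inlet recycling, which keeps the density stationary), and the slow-time
phase of moving blood arises from the changing path lengths.

## Beamforming

`beamform_series()` performs per-event 3D delay-and-sum on complex
baseband with phase rotation `exp(+2i pi f0 tau)`, then averages events
coherently (both OPW orientations together, or separately with
`combine = "split"` for XDoppler). Knobs that shape the point-spread
function:

* receive dynamic aperture: Hann over a width `z / rx_fnumber`
  (default f-number 1) - sets the receive-axis width (~1.4 lambda f#) and
  its -60 dB-class side-lobe floor;
* synthetic transmit apodization (`tx_apodization`, SA/HSA only): Hann
  across the transmit-element grid. The event dimension of an SA
  acquisition *is* a spatial aperture; windowing it is standard synthetic
  aperture practice and is what gives SA/HSA their deep side-lobe floor.
  Plane-wave angle compounding remains unweighted;
* sampling: the DAS samples at the echo arrival plus the envelope-peak
  time of the effective pulse (group-delay correction), which keeps the
  PSF peak on the true target position;
* default grids: half-wavelength lateral, quarter-wavelength axial
  (`default_grid()`); widths are measured with sub-voxel (spline)
  interpolation so the grid contributes < 2%.

## Image-quality metrics

FWHM is measured at -3 dB on the squared (intensity) profile through the
3D peak. Side lobes are read off the two lateral profiles over the full
field of view: main lobe out to the first local minima, maximum beyond
them, worst axis. Grating lobes are searched in the 3D region whose
direction sines from the target fall in the band predicted from steering
and pitch (`grating_sine_band()`); at 150 um pitch and 164 um wavelength
only steered transmits have propagating replicas (about 51-87 degrees).

Two honest caveats from the synthetic PSF study, at the default
configuration (single target at 4.8 mm):

* the SA/HSA lateral profile has a flat stationary-phase skirt at about
  -35 dB beyond +-3 mm - a consequence of purely one-way transmit
  focusing per axis (it is independent of pulse length and directivity).
  Within +-3 mm the floor is -50 dB or lower. Reported side-lobe levels
  therefore depend on the profile extent, which profile plots in the
  literature rarely state.
* energy localisation (>= 50% of image energy within a 3x3x3-voxel box
  around the target) holds for SA (0.87), OPW32+32 (0.76) and OPW16+16
  (0.56), but not for OPW8+8 (0.41), whose compound beam is wider than
  the box - consistent with that sequence's poor standing in the design
  study.

## Clutter filtering and Doppler products

`svd_clutter_filter()` decomposes the Casorati matrix (voxels x slow
time) and removes the first `ceil(0.15 n)` modes (tissue) and the last 50
(noise), the in vivo rule. Two methodological notes:

* the fractional rule presumes clutter whose rank grows with the
  ensemble, as moving tissue does. A digital phantom with strictly static
  gel has clutter of rank ~1; on such data the 15% rule increasingly
  removes *blood* modes (97% of blood energy sits in the first ten modes
  of a 400-frame tube acquisition) and contrast falls with acquisition
  time, the opposite of what physical flow phantoms show. The in vitro studies
  therefore fix the removed low modes (`low_count = 2`); the fractional
  default is untouched.
* re-running the rank-counting filter is *not* idempotent (zeroed modes
  shift everyone's rank), so the projection property is exposed and
  tested through the retained basis (`project_clutter_basis()`).

Power Doppler is the slow-time mean power; signed power Doppler takes its
sign from the lag-1 autocorrelation phase; `xdoppler_power()` correlates
the two OPW orientations instead of summing them, cancelling noise terms
that are independent between orientations. Spectral Doppler uses a
30-point Hann STFT at 50% overlap averaged over a 3x3x3 ROI, velocities
mapped by `v = c f_d / (2 f0)`; the resistive index uses per-cycle
`(peak systolic - end diastolic) / peak systolic`, and a 95th-percentile
spectral envelope is available where a waveform must be extracted from a
spectrogram.

### The flow-contrast study

The desk-scale stand-in for the flow-phantom study uses a 500-um tube at
3 mm depth carrying 1 cm/s flow (blood 10 scatterers/mm^3, gel 5/mm^3),
channel SNR 0 dB, 20 kHz PRF, and ensembles of 100/200/400 compound
frames. Two conditions deserve comment. Blood echoes are set *below* the
per-sample noise floor because that is the physical regime of
microvascular Doppler (blood backscatter is tens of dB below tissue);
with strong blood the background statistics are dominated by PSF-skirt
leakage and contrast saturates. The background mask is a depth-offset
shell rather than a lateral guard ring, because the axial PSF falls off
much faster than the lateral skirts. Under these conditions the
expected orderings reproduce: contrast grows monotonically with
ensemble length, OPW32+32 >= OPW16+16 >= HSA at matched 1.28-s duration,
and XDoppler SNR is at least the coherent-sum SNR.

## Tissue pulse waves

`kasai_phase_shift()` estimates axial tissue velocity from the lag-1
autocorrelation phase of the *unfiltered* IQ series,
`v = c fr arg(s_t conj(s_{t-1})) / (4 pi f0)`, with a 3x3x3x2 averaging
kernel before the argument; displacements above lambda/8 per frame wrap.
`extract_pulse_component()` keeps the five leading SVD temporal modes of
the Kasai series and unmixes them with a seeded symmetric fixed-point ICA
(tanh contrast, whitening by eigen-decomposition, symmetric
decorrelation); the pulse is the component with the largest spectral
fraction in the cardiac band (0.7-3 Hz plus first harmonic), sign-fixed
so the dominant deflection is positive, with an error if no component
reaches a 0.3 band fraction. Peaks come from an adaptive
median + 2 MAD threshold with a 0.33 s minimum interval; transit times
pair each deformation peak with the latest R-peak at most 0.6 s before
it; velocity is path length over transit time. Widths are measured at
half prominence with linear interpolation.

## Longitudinal registration

Vesselness is a Frangi-type multi-scale Hessian tubularity measure
(gamma-normalised scales, bright-tube eigenvalue signs, alpha = beta =
0.5, energy term calibrated per scale), normalised to [0, 1];
segmentation thresholds it and drops 6-connected components below 27
voxels. Rigid registration maximises normalised cross-correlation over
the common support with a deterministic coarse translation grid search
followed by Nelder-Mead at two resolutions (the NCC surface has shallow
local minima once structures stop overlapping, which a pure simplex
start falls into); transforms are ZYX Euler about the volume centre,
trilinear interpolation during optimisation and Catmull-Rom tricubic for
final resampling. Across seeded transforms up to ~1 mm and ~5 degrees on
noisy tube fixtures, recovery is within 0.1 mm and 0.5 degrees. The
common-volume fraction of a transform is evaluated on a cell-centred
64^3 lattice.

## Hemodynamic responses

The thermal protocol (30 s baseline, 30 s cold, 60 s hot at 0.5
volumes/s) is coded as a tri-level regressor (0/-1/+1), so one
correlation captures both phases; a 0/1 hot-only coding is available.
Voxel-wise Pearson correlations are Fisher-transformed
(`z = atanh(r) sqrt(n - 3)`) and thresholded with a Bonferroni count
equal to the imaging volume over the -3 dB PSF ellipsoid volume, as a
multi-one-tailed rule on |z|.

The response model is a gamma-difference kernel (shape/scale
parameterisation, negative-lobe weight bounded by 1) convolved with the
stimulus step - for a unit step, a cumulative difference of gammas. Rise
time is the kernel mode; duration is the SD of the normalised positive
part. `fit_hrf()` runs seeded multi-start Levenberg-Marquardt on the
window from the hot onset, with the pre-cold baseline anchoring the
offset. The PBV generator inverts this model: its kernel is solved from
the target mode and SD (defaults 14.3 s and 8.4 s with a +113% plateau),
and its cold response - for which no fitted form exists - is a
gamma-shaped transient dip (shape 2, scale 3 s, 27% peak), a modelling
choice flagged as such. Noiseless round trips recover the timing
parameters within 1%; at 5% noise the mean rise-time bias over 50 seeds
stays below 10%.

## What the synthetic studies do not show

The generators emulate geometry, kinematics and first-order statistics,
not tissue: no attenuation-driven depth dependence, no physiological
clutter spectrum (static gel stands in for tissue), no probe motion, no
hardware pulse asymmetry, and point scatterers rather than resolved
cytoarchitecture. Green tests therefore validate the *processing chain*
and its internal consistency against closed forms and independent
oracles, not clinical performance. Where the reference simulation table
could not be reconciled with the printed sequence parameters (the
small-angle plane-wave side-lobe levels), the discrepancy is documented
rather than absorbed into the fixtures.

## Problem sizes and runtimes

The test suite and the acceptance studies run single-threaded at desk
scale: PSF studies beamform a 118 x 118 x 25 half-wavelength slab from
16-64 transmits; the flow study processes 400-frame (1.28 s) ensembles
in 64-frame blocks on a ~45k-voxel grid; Monte-Carlo suites use 20-200
replicates. Every stochastic step draws from an explicit seed.
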