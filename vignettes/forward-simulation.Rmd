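---
title: "Forward simulation of in vivo-like proton MRS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forward simulation of in vivo-like proton MRS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsforge)
```

## The model

`mrsforge` simulates single-voxel proton MR spectra the way linear-combination
fitting software models them, run forward. A noiseless acquisition is the sum
over the basis set,

$$f(t) = \sum_n M_n\,\mathrm{basis}_n(t)\,
  e^{-d_n t - g t^2}\, e^{-2\pi i\,\Delta f_n t}\,
  \frac{1}{R}\sum_{r=1}^{R} e^{-2\pi i\,\Delta\omega_r t},$$

to which baseline and residual-water curves, SNR-defined complex Gaussian
noise, zero- and first-order phase offsets and an eddy-current phase term are
applied, in that order; an optional coil stage then turns the FID into $C$
transients with per-transient sensitivities, SNR levels and frequency/phase
drifts. Post-processing (apodization $e^{-t\,TL}$, zero-filling, FFT,
crop/resample) is a separate, explicit step, so datasets can be exported at
any stage from raw transients to processed spectra. Every quantity that is
drawn at random is drawn from a seeded, recorded stream: the exported
parameter record re-creates its spectrum bit for bit, which is the point of
simulating rather than acquiring.

The assumptions are those of the fitting packages the model mirrors: a shared
acquisition grid for all basis functions, Voigt lineshapes (one Lorentzian
rate per metabolite, one Gaussian rate for the metabolite group and one for
macromolecules/lipids), a linear B0 gradient over the voxel, and nuisance
signals that are smooth in the spectral domain.

## Conventions that everything else depends on

One spectral transform is used package-wide: the unnormalised inverse-type
DFT with the zero-frequency bin shifted to the centre. Consequences, each
pinned by a unit test:

* a time-domain factor $e^{-2\pi i f t}$ displaces a resonance by $+f$ Hz,
  i.e. toward **higher** ppm — so a positive mean B0 offset of 10 Hz moves
  every peak by +10 Hz, and the long-time-constant limit of the eddy term is
  a $+A_0$ Hz shift;
* the time axis starts exactly at $t = 0$; acquisition delay is modelled
  as first-order phase, not as a hidden dead time;
* the ppm axis is stored ascending and centred on `ppm_ref` (4.65 ppm,
  water); the conventional high-ppm-left orientation is applied only when
  plotting;
* noise is drawn in the time domain with SD $\sigma/\sqrt{n}$ per channel so
  that the spectral real-channel SD equals the requested
  $\sigma = \mathrm{ref\_height}/\mathrm{SNR}$ under this transform.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `spectral_width` | Hz | 2000 | standard short-echo 3T single-voxel readout |
| `carrier_frequency` | MHz | 127.7 | proton frequency at 3 T |
| `ppm_ref` | ppm | 4.65 | water reference; also the first-order-phase pivot |
| `snr` | linear | fixed 15 | reference SNR of the study conditions |
| `d` | 1/s | uniform 2–10 | Lorentzian rate; FWHM contribution $d/\pi$ Hz |
| `g_metab` | 1/s² | uniform 5–50 | shared Gaussian broadening of the metabolite group |
| sensitivity | — | Normal(1.0, 0.5) clamped [0, 2] | default coil-sensitivity sampler |
| transient SNR | linear | $\mathrm{snr}_0/\sqrt{C}$ × Normal(1, 0.05) | averaging then recovers $\mathrm{snr}_0$ |
| eddy `A0`, `tc0` | Hz, s | uniform 0–5, 0.1–0.3 | amplitudes/time constants in the range where the term distorts rather than merely shifts |
| baseline window | fraction | 0.15 | wide uniform kernel → broad smooth curves |
| water window | fraction | 0.02 | narrow kernel → irregular residual-water region |

The per-transient SNR scaling deserves a note: the only reading under which
"scale the target SNR by the number of coils" and "averaging gains
$\sqrt{C}$" are mutually consistent is a per-transient target of
$\mathrm{snr}_0/\sqrt{C}$, which is what the sampler implements. The 5%
"narrow normal" spread is a package choice, small enough to preserve the
mean target.

## The B0 sub-voxel model

The voxel is divided per axis into the number of anatomical-image voxels it
spans (`grid_shape_from_voxels`), and each cell contributes the field value
at its **centre**: coordinates $u_k = (2k-1-G)/G$. Midpoint sampling keeps
the map mean exactly at $\mu$ for every grid size and converges to the
continuum (sinc) damping at second order in $1/G$; corner-inclusive sampling
was rejected because its $1/G$ endpoint bias never reaches the continuum
limit to within 1% at realistic grid sizes. The field at the voxel *edge* is
$\mu \pm d_x$; the sampled extremes sit a factor $(G-1)/G$ inside, which is
the physically meaningful statement for cell-centred maps. The modulator sum
is normalised by $R$ — an unnormalised sum would scale the signal with grid
resolution, contradicting the damping behaviour the model exists to produce.
Non-linear gradient profiles plug in as per-axis coordinate transforms.

## The nuisance generator

Both the baseline and the residual water come from one bounded, smoothed
pseudo-random walk. A cumulative-sum Gaussian walk is detrended against the
straight line through *its own* endpoints; the fluctuations are rescaled so
their range equals `upper_bound − lower_bound`, clipped to half that range,
added to the straight `start`→`end` trend, clipped to the bounds, and
smoothed with a uniform kernel of `window_size × length` samples (reflected
edges; smoothing is a convex combination, so boundedness survives). Two
details are deliberate design choices:

* detrending uses the walk's own endpoint line rather than the output trend —
  this is the only construction under which `std = 0` degenerates to the pure
  trend line, which we treat as the defining behaviour of the generator;
* the out-of-bounds adjustment is hard clipping (of the deltas, then of the
  final walk). Reflection would be a drop-in alternative; clipping is the
  simplest operator that guarantees the bounds for *every* configuration,
  including off-centre `start`/`end`.

The imaginary channel is synthesised by rotating every positive-frequency
component of the curve's conjugate-domain representation by a quarter cycle
(a discrete Hilbert transform): for a Lorentzian absorption input the output
is the matching dispersion curve, accurate away from the span edges provided
the curve has decayed within its span. Curves are generated on their own
axis, resampled onto the acquisition ppm axis (zero outside their span),
scaled relative to the noiseless metabolite spectrum maximum, and carried
into the time domain by the inverse spectral transform, where they are added
to the FID.

## Numerical choices

* **Interpolation** for cropping/resampling is cubic Hermite with
  modified-Akima slope weights, implemented in the package; it is exact at
  nodes, reproduces affine data, and avoids spline overshoot next to narrow
  peaks. (The classic Akima weighting was not used; the modified weights
  handle flat regions without oscillation.)
* **SNR measurement** follows the spectral definition: maximum real-channel
  peak height over the SD of the real channel in a signal-free region
  (default: the highest-ppm 10% of the axis, which the toy bases leave
  empty). At SNR 15 the max-statistic gives the estimator a small (~2%)
  upward bias relative to the requested value; the calibration tests average
  100 seeded realisations for this reason.
* **Degenerate inputs**: zero-amplitude sets return the zero FID; `std = 0`
  walks return the trend; `snr = Inf` is the documented no-noise sentinel;
  negative broadening rates are rejected rather than silently growing the
  FID.
* **Seeding**: every random draw happens under `withr::with_seed` with
  sub-seeds derived arithmetically from the master seed (all below $2^{31}$),
  so batches are reproducible end to end and each exported record carries the
  seeds it needs.

## What the toy basis does and does not emulate

The built-in generator produces exponentially damped singlets (NAA 2.01,
Cr 3.03, Cho 3.22 ppm by default), normalised so one amplitude unit equals a
spectral maximum of 1 — the concrete meaning of "one basis unit = 1 mM".
That suffices to exercise every operator in the pipeline (shifts, widths,
damping, SNR, phases are all measurable against closed forms), and it is
what the test suite and the acceptance script run on. It does **not**
reproduce J-coupled multiplets, sequence- and vendor-specific lineshapes, or
macromolecular backgrounds of real basis sets; passing tests therefore
demonstrate the correctness of the forward operators, not the in vivo
realism of any particular simulated dataset. Real basis sets (one complex
FID per metabolite on a shared grid) can be supplied through the basis
container (`read_basis`).

## Problem sizes

The reference conditions used throughout the documentation and tests are a
2048-point, 2000 Hz, 3 T grid; calibration checks use 100–200 seeded noise
realisations, the sensitivity sampler is characterised at $10^5$–$10^6$
draws, and batch-level checks simulate a handful of full spectra — sizes at
which every documented tolerance is comfortably resolved on a single CPU.
Batches are simulated spectrum-by-spectrum from per-record seeds, so memory
scales with one spectrum, not with the batch.

## Known limitations

* Moiety-level T2 values and frequency shifts are not modelled (per-basis
  values only); temperature/pH dependences enter only through user-supplied
  shift distributions.
* The baseline generator is statistical, not physical: it brackets plausible
  baselines rather than claiming any one of them is in vivo truth.
* Eddy currents follow the single-exponential two-parameter model; multi-
  exponential gradient histories are out of scope.
* Spatial (multi-voxel) acquisitions, editing schemes and 2D experiments
  are out of scope.

## A complete run

```{r, eval = FALSE}
grid <- build_grid(2048, 2000, 127.7, 4.65)
basis <- default_toy_basis(grid)
spec <- default_sampling_spec(basis$names)
spec$transients <- list(n_transients = 8L)

ds <- simulate_dataset(spec, basis, n = 64, seed = 2026)
export_dataset(ds, "run01")            # dataset.json + dataset.nii (+ sidecar)

# ground truth round trip
res <- simulate_spectrum(ds$samples[[1]], basis)
identical(res$fid, ds$fids[, 1])       # TRUE, bit-exact
```
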