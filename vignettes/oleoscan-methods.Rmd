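---
title: "Methods: scanning-SAXS and micrograph orientation analysis of USW-structured oleogels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning-SAXS and micrograph orientation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oleoscan)
```

## The problem

Monoglyceride (MG) oleogels are edible oils structured by a network of
lamellar MG crystal platelets. Treating the molten gel with an ultrasound
standing wave (USW) during setting collects crystalline material into the
wave's nodal planes, producing periodic bands (spacing half the acoustic
wavelength: `half_wavelength_spacing(0.65)` = 0.325 mm for a 2.25 MHz wave
in oil) and can orient the platelets. `oleoscan` quantifies this
structuring from two complementary measurements:

* **scanning SAXS**: reduced 2D scattering patterns on a
  (q, $\chi$) grid, one per point of a raster scan (typically
  101 × 101 points at 20 µm steps), and
* **bright-field micrographs**, analyzed by a 2D-FFT angular power
  spectrum.

No raw scan data ships with the package; instead a synthetic generator
produces both kinds of data with known ground truth, so every stage of
the pipeline is testable end to end.

## SAXS reduction

For each pattern, intensity is held on a grid of scattering-vector
magnitude $q$ (Å⁻¹) by azimuthal angle $\chi$ (degrees), with a boolean
mask. Detector gaps (troughs at roughly 25° intervals) are *masked, never
zeroed*: every statistic below averages over valid bins only, and a
fully masked row or bin propagates as a flagged missing value.

**Radial profile.** `radial_average()` takes the per-$q$ mean over valid
$\chi$ bins. Three quantities are extracted from it:

* **d-spacing.** A Gaussian plus linear baseline is fitted inside a
  window (default 0.10–0.16 Å⁻¹) around the lamellar reflection at
  $q \approx 0.13$ Å⁻¹, by Levenberg–Marquardt least squares
  (`minpack.lm`), with starting values from the discrete argmax and the
  background-subtracted second moment. Bragg's law gives
  $d = 2\pi/q_\mathrm{peak}$; with $q_\mathrm{peak} = 0.1308$ Å⁻¹,
  $d = 48.0$ Å $= 4.8$ nm. The only established convention here is the
  Gaussian peak shape; the linear baseline and the moment-based
  initialization are this package's choices, made so the fit is
  deterministic and flags (rather than silently accepts) estimates
  pinned at the window bounds.
* **Correlation length.** The Scherrer relation $\xi = 2\pi/\Delta q$ is
  applied to the fitted full width at half maximum
  ($\Delta q = 2\sqrt{2\ln 2}\,\sigma$), uncorrected for instrument
  resolution. Internally $q$ is strictly Å⁻¹ and $d$, $\xi$ Å; the
  reporting layer divides by 10 for nm. Published tables in this field
  sometimes carry $\xi$ values on another scale than a literal
  $2\pi/\Delta q$ in these units; `oleoscan` never rescales — and all
  *comparative* statements (percent changes via `scherrer_ratio()` or
  `percent_increase()`) are unit-independent, because $\xi \propto
  1/\Delta q$.
* **Porod exponent.** `fit_power_law()` regresses $\log I$ on $\log q$
  over the low-$q$ range, default 0.005–0.05 Å⁻¹. The default follows
  the explicitly stated fitting range even though the power-law *region*
  is sometimes described as ending at 0.04 Å⁻¹; the range is a plain
  argument, so either convention is one keystroke away. The surface
  fractal dimension is $D_s = 6 - |P|$ (e.g. $|P| = 3.58 \Rightarrow D_s
  = 2.42$). Non-positive intensities (possible after background
  subtraction upstream) are excluded with a warning rather than
  silently dropped.

**Azimuthal profile and orientation.** `azimuthal_profile()` averages
over the band $q \in [0.11, 0.15]$ Å⁻¹ bracketing the lamellar ring.
The Hermans orientation factor is

$$ f_2 = \tfrac12\left(3\langle\cos^2\chi\rangle - 1\right), \qquad
\langle\cos^2\chi\rangle = \frac{\int_0^{\pi/2} I(\chi)\sin\chi\cos^2\chi\,d\chi}
                                {\int_0^{\pi/2} I(\chi)\sin\chi\,d\chi}, $$

ranging from $-0.5$ (plane normals perpendicular to the director)
through 0 (isotropic, $\langle\cos^2\chi\rangle = 1/3$) to $+1$
(parallel). The director is $\chi = 0°$, the horizontal scan axis.
Numerical choices:

* **Folding.** The integral is stated on $[0, \pi/2]$ but detector data
  span 360°. Platelet orientation is an axis, so $\chi$, $180°-\chi$,
  $180°+\chi$ and $360°-\chi$ are equivalent; their valid bins are
  averaged onto $[0°, 90°]$. This makes the stated integral well defined
  on full-circle data and makes the OF exactly invariant under a 180°
  rotation of the profile.
* **Quadrature.** Trapezoid on the (possibly nonuniform) folded grid;
  masked bins are dropped, never interpolated — no intensity is invented
  inside detector gaps.
* **Degenerate limit.** A profile concentrated in the $\chi = 0°$ bin
  makes both sin-weighted integrals vanish ($\sin 0 = 0$). The
  implementation detects a vanishing denominator and falls back to the
  plain intensity-weighted mean of $\cos^2\chi$, which is the analytic
  limit of the ratio as the distribution concentrates at 0 and yields
  the required $f_2 = 1$.
* **Smoothing.** The circular boxcar of kernel size 30
  (`smooth_azimuthal()`) is for display and interpretability of
  azimuthal profiles; it is *not* applied before `hermans_of()` by
  default, since whether published OF values were computed on smoothed
  profiles is not stated. Callers can smooth first if they want the
  other convention; for the smooth ring shapes involved the difference
  is small.

## Scan maps and band detection

`reduce_scan()` applies the reductions per point; `build_maps()` places
them on the rectangular position grid (off-grid or duplicate positions
are errors; failed fits are flagged, never interpolated).

`estimate_band_spacing()` projects the map along each candidate band
axis (x and y by default — nodal bands are axis-aligned in this
geometry), picks the axis with the larger projection standard deviation,
and takes the lag of the first non-zero-lag local maximum of the
unbiased, variance-normalized autocorrelation. Autocorrelation is used
instead of an FFT peak deliberately: 0.3 mm is exactly 15 steps of the
20 µm grid, while the 2 mm window holds a non-integer 6.67 periods, so
DFT bins could only report 0.33 or 0.29 mm. The autocorrelation value at
the peak lag doubles as a confidence score; a constant or aperiodic map
yields a low-confidence result with a warning instead of an error.

`map_summary()` reports mean/median/sd of each map inside versus outside
a band mask, plus the integer-rounded percent change of means — the form
in which correlation-length increases are conventionally quoted (means
1440 → 1770 nm give +23%; medians, equivalently fwhm medians
0.0043 → 0.0034 Å⁻¹, give +26%).

Two acoustic geometry helpers close the loop to the treatment hardware:
`half_wavelength_spacing()` (nodal spacing $\lambda/2$) and
`near_field_distance()` ($N = D^2/4\lambda$; a 50 mm transducer at
0.65 mm wavelength gives 961.5 mm ≈ 1 m, the scale on which local
pressure inhomogeneities can persist).

## Micrograph FFT pipeline

Five steps, mirroring the classical fiber-orientation FFT analysis:
(i) import (`read_micrograph()`, gray in $[0,1]$);
(ii) `complement_and_mask()` — invert about the representable maximum
and multiply by a centered circular Gaussian window;
(iii) `power_spectrum()` — squared magnitude of the 2D DFT,
center-shifted, normalized to unit total power;
(iv) `apply_bandpass()` — sharp binary annulus, default
0.025–0.25 µm⁻¹, i.e. element sizes 4–40 µm;
(v) `polar_integrate()` — each pixel assigned to the integer degree
nearest its polar angle and summed, so the 360 bins exactly partition
the in-band power (conservation is exact, and is tested as such).

Design choices where the procedure is underdetermined:

* **Window width.** $\sigma = 0.25 \times \min(\mathrm{h, w})$,
  configurable. Without the window, the non-periodic image boundaries
  leak power into a bright axis-aligned cross that swamps orientation
  differences; 0.25 suppresses the cross by well over half while
  retaining the central content.
* **Sharp bandpass.** Binary annulus, no taper. The low cut removes
  band shading and windowing residue near the origin; the high cut
  removes the ring artifacts the circular window introduces (first at
  0.3 µm⁻¹) before they alias near the corners.
* **No zero padding** by default; available upstream by embedding the
  image if needed, but not required for these image sizes.
* **Savitzky–Golay smoothing** of the angular spectrum: window 15°,
  order 3, wrap-around boundary (the filter parameters are not fixed by
  convention; these preserve features wider than ~15° and are exact on
  cubic segments). Via `signal::sgolayfilt`.
* **Normalization** to unit total power per image, before the bandpass,
  so angular spectra are comparable across images.
* **Angle convention** matches the SAXS director: 0° = +x, increasing
  counterclockwise in the matrix convention shared by both pipelines.

`anisotropy_index()` summarizes a spectrum by axial circular statistics
on the doubled angle: preferred angle (mod 180°) and resultant length in
$[0,1]$. Note the angular power spectrum of elongated objects peaks
*perpendicular* to their long axis (Fourier rotation property), so
platelets at axis $\theta$ produce a preferred spectrum angle of
$\theta + 90°$.

`inverse_check()` implements the manual verification step: zero the
out-of-band complex coefficients and invert; with an all-pass band the
round trip reproduces the masked input to numerical precision.

## Synthetic data: what it emulates, and what it does not

**Patterns.** Expected intensity is
$B q^P + A\,e^{-4\ln 2\,(q-q_0)^2/\Delta q^2}\, g(\chi)$ with an
optional broad shoulder at 0.04–0.08 Å⁻¹ (emulating scattering from
Kapton holder walls; off by default, as a nuisance term). The azimuthal
weight $g$ is a 180°-periodic von Mises density in the doubled angle,
$g(\chi) = e^{\kappa\cos 2(\chi-\chi_\mathrm{pref})}/I_0(\kappa)$ —
chosen because platelet orientation is an axis, the law has a single
concentration parameter, and the closed-form normalization keeps the
circular mean of $g$ at 1, so radial profiles are independent of
$\kappa$ (total ring counts are conserved). Defaults are the study
conditions: $q_0 = 0.1308$ Å⁻¹, $\Delta q = 0.0045$ Å⁻¹, $P = -3.5$,
10°-wide detector gaps every 25°, Poisson counting noise. The ring
amplitude default (1000 counts at the azimuthal mean) is a choice for a
well-exposed synchrotron exposure; it sets the noise level of all
recovery tests.

**Scans.** 101 × 101 points at 20 µm steps, sinusoidal band modulation
of period 0.3 mm along the axis normal to the bands. All per-point
parameters follow one contrast-scaled weight
$w = (1 + c\cos 2\pi u/p)/2$: amplitude $\propto 2w$, concentration
$\kappa = \kappa_\mathrm{in} w$ (with $\kappa_\mathrm{in}$ obtained by
numerically inverting the OF–$\kappa$ quadrature map for `of_in_band`),
and $\xi$ interpolating `xi_out_band` → `xi_in_band` (defaults 1460 and
1850 Å, i.e. $2\pi/\Delta q$ for fwhm 0.0043 and 0.0034 Å⁻¹). At
$c = 1$ the in-band targets are attained exactly at band centers; at
$c = 0$ every ground-truth map is constant. `of_in_band = 0.4` and
`band_contrast = 0.5` are the defaults — moderate orientation and
clearly visible but noisy bands. Per-point Poisson streams derive from a
single scan seed, so adding stages never perturbs other points and the
whole scan is bit-reproducible.

**Micrographs.** Background 0.7 with sinusoidal band shading plus dark
elliptical platelet silhouettes; lengths/widths lognormal (20% spread)
about 20 × 4 µm, orientations axial von Mises about the band axis
(sampled by Best–Fisher rejection), Gaussian blur and additive noise.
The default 1 µm/px pixel size is an explicit placeholder — low-power
bright-field pixel sizes vary with camera and objective — and is a
config field precisely because it is uncertain.

What the generators do **not** emulate: smearing by beam size and
detector point-spread, polymorph transitions and multi-peak patterns,
depth-of-field blur gradients, platelet overlap occlusion and
out-of-focus scattering backgrounds, or any acoustic physics (the band
profile is imposed, not simulated). Passing recovery tests therefore
demonstrates correctness of the *reduction pipeline* under realistic
counting statistics and masking — not robustness to every instrumental
artifact of real beamline or microscope data.

## Problem sizes and determinism

The test suite and the acceptance script regenerate all inputs from
code. The full-scale checks use one 101 × 101 scan (its pattern grid
150 $q$ × 72 $\chi$ bins — azimuthal bins of 5°, sufficient for the
intensity and OF maps) for band-spacing and OF-contrast recovery, with
peak fits verified on a 9-point spread of the same scan; smaller grids
(31–61 points per side) are used where a property does not need the full
field. Micrograph checks use 256–384 px images with up to 500 platelets
so that orientation-sampling error stays well below the 5° recovery
tolerance being tested. Every stochastic step draws from an explicit
seed argument; identical configs give bit-identical outputs.

## Known limitations

* The Scherrer relation is applied uncorrected; beam-size integration
  means $\xi$ conflates single-platelet thickness with stacks of aligned
  platelets, so treat $\xi$ maps as relative structure measures.
* The Hermans OF assumes uniaxial orientation; for these samples it is
  an estimate, not a full orientation distribution.
* Band-spacing estimation assumes near-axis-aligned bands; a full
  angular search is out of scope of the default (axis set is an
  argument).
* The micrograph pipeline reports orientation of image texture in the
  4–40 µm band; it does not segment or count platelets.
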