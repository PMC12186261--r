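# oleoscan

Quantitative analysis of ultrasound-standing-wave (USW) structured
monoglyceride (MG) oleogels, for researchers characterizing how
acoustic treatment reorganizes the lipid-crystal network. When a gel
sets inside a standing wave, crystalline platelets collect in the nodal
planes (spaced half the acoustic wavelength, ~0.3 mm at 2.25 MHz) and
can become oriented. `oleoscan` measures both effects from the two
standard observables:

* **Scanning SAXS** — reduced 2D patterns on a (q, χ) grid, one per
  raster-scan point. Per pattern the package extracts:
  * lamellar d-spacing from the diffraction peak near q = 0.13 Å⁻¹ by
    a Gaussian + linear-baseline fit and Bragg's law *d* = 2π/q_peak
    (0.1308 Å⁻¹ → 4.8 nm);
  * crystal correlation length from the peak width via the Scherrer
    relation ξ = 2π/Δq;
  * Porod exponent *P* from a log–log fit of the low-q background
    I(q) = B q^P over 0.005–0.05 Å⁻¹, and the surface fractal
    dimension D_s = 6 − |P|;
  * Hermans orientation factor
    f₂ = (3⟨cos²χ⟩ − 1)/2, with the sin-weighted moment
    ⟨cos²χ⟩ = ∫ I(χ) sin χ cos²χ dχ / ∫ I(χ) sin χ dχ on [0°, 90°],
    from the azimuthal profile over q = 0.11–0.15 Å⁻¹
    (−0.5 perpendicular, 0 isotropic, +1 parallel to the director).

  Per-point results become spatial maps; the nodal-band spacing is
  estimated from the autocorrelation of the map projection, and
  in-band/out-of-band summaries quantify the structuring.

* **Bright-field micrographs** — a five-step 2D-FFT analysis
  (complement → Gaussian window → power spectrum → sharp annular
  bandpass, 0.025–0.25 µm⁻¹ ≙ 4–40 µm elements → polar integration to
  an angular power spectrum), plus Savitzky–Golay smoothing, an
  inverse-transform verification, and an axial circular-statistics
  anisotropy index.

Because raw beamline scans are rarely shareable, the package ships
synthetic-data generators with known ground truth for patterns, whole
raster scans, and micrographs; every stage is tested against them.

## Worked example

```r
library(oleoscan)

## one synthetic pattern: oriented ring + power-law background + noise
p <- simulate_saxs_pattern(saxs_sim_config(kappa = 2, noise = TRUE, seed = 42))
fit_main_peak(radial_average(p))
#> q_peak = 0.1308 1/A (d = 48.03 A = 4.80 nm); fwhm = 0.00450 1/A (xi = 1397 A)
fit_power_law(radial_average(p))
#> I(q) = B q^P: B = 3.881e-06, P = -3.558 (|P| = 3.558, D_s = 2.442); rms log-residual 0.156 (n = 35)
hermans_of(azimuthal_profile(p))
#> Hermans OF = 0.5530  (<cos2 chi> = 0.7020, 19 folded bins)

## a banded raster scan -> maps -> band spacing and in/out contrast
scan <- simulate_scan(scan_sim_config(nx = 61, ny = 31, seed = 1),
                      saxs_sim_config(noise = TRUE))
res  <- reduce_scan(scan, what = c("intensity", "of"))
maps <- build_maps(res)
estimate_band_spacing(maps)
#> band spacing 0.300 mm along x (lag 15 steps, confidence 1.00)
map_summary(maps, matrix(scan$truth$in_band, 61, 31))[, c("metric", "mean_in", "mean_out", "pct_change")]
#>     metric mean_in mean_out pct_change
#>  intensity 131.563   74.047         78
#>         of   0.269    0.135         98

## micrograph orientation analysis
img <- simulate_micrograph(micrograph_sim_config(kappa = 4, seed = 3))
anisotropy_index(micrograph_aps(img))
#> preferred angle 179.0 deg, anisotropy 0.565

## acoustic geometry of the treatment
near_field_distance(50, 0.65)     # mm: ~1 m for a 50 mm transducer
#> [1] 961.5385
half_wavelength_spacing(0.65)     # mm: nodal spacing of a 0.65 mm wave
#> [1] 0.325
```

Reading the output: the peak fit recovers the generator's ring
(q₀ = 0.1308 Å⁻¹, Δq = 0.0045 Å⁻¹ → ξ = 1397 Å) and the 4.8 nm lamellar
repeat; the fitted |P| sits near the generating 3.5 with
counting-statistics scatter. The scan maps show the imposed 0.3 mm
bands (15 steps of the 20 µm grid, detected exactly) and higher
intensity and orientation factor inside the bands. The micrograph's
preferred spectrum angle of ~179° ≈ 0° (mod 180) is perpendicular to
the platelets, which were drawn about the vertical (90°) band axis.

A command-line front end (`exec/oleoscan`) exposes the same pipeline as
subcommands (`simulate-scan`, `reduce`, `map`, `simulate-micrograph`,
`micrograph`), driven by a YAML config; each run writes its fully
resolved config next to its outputs.

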