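# sacchmon

Monitoring enzymatic saccharification of lignocellulosic particle fractions
from time-lapse reactor images, sugar-release kinetics and low-field NMR
relaxometry — with a seeded synthetic-data generator so the whole stack is
testable without instrument data.

## What it computes

When milled plant biomass (e.g. maize shoot fractions) is hydrolyzed by
cellulases in a stirred imaging reactor, particles can dissolve whole, erode,
or fragment. sacchmon extracts the quantities that distinguish these
mechanisms:

* **Gray-level granulometry** (segmentation-free image analysis): after
  tophat background removal, the total gray-level sum of a frame proxies the
  relative amount of particles, and the pattern spectrum from morphological
  openings by linear structuring elements at 0° and 90° gives the
  distribution of the average projected particle length,

  `density(s_i) = G(s_{i-1}) - G(s_i)`, with `G(s)` the gray mass retained
  after opening at size `s` (16.4 µm steps up to ~1075 µm by default),

  condensed into a gray-level mean size and size classes
  ([0–45], [45–225], > 225 µm).
* **Saccharification kinetics**: one- or two-component saturating exponential
  fits `y(t) = Σ A_i (1 − e^(−k_i t))` (mirrored for decreasing series) with
  deterministic multi-start, AICc order selection, and the half-change time
  `t½` (time to 50% of the fitted full range; `ln 2 / k` for one component).
* **CPMG relaxometry**: inverse Laplace transformation of the decay into a
  non-negative T2 spectrum, `min ‖Kp − y‖² + λ‖p‖₁, p ≥ 0`, solved exactly by
  active-set non-negative least squares with a discrepancy-principle λ;
  water-population detection (T2 peaks, P2 proportions), linear
  T2-to-pore-diameter calibration, and the water content in the
  enzyme-accessible [5, 15) nm pore band.
* **Cross-fraction statistics**: OLS regressions with R², summary statistics
  (n−1 sd, RSD%), weighted D10/D50/D90 percentiles and span
  `(D90 − D10)/D50`, over packaged characterization tables of a maize shoot
  powder and its six dry-fractionation fractions.
* **Synthetic data**: seeded particle-image time series under known
  degradation scenarios (dissolve / shrink / fragment) with coupled sugar
  curves, plus forward-modelled CPMG decays and kinetic series, all with
  ground-truth tables.

## Worked example

Simulate a 7-h hydrolysis in which particles dissolve whole (45%
recalcitrant, hazard 0.172 h⁻¹), measure it with the image pipeline, and fit
the kinetics:

```r
library(sacchmon)

spec <- particle_population_spec(n_particles = 120, length_median_um = 170,
                                 length_log_sd = 0.25, width_median_um = 50,
                                 width_log_sd = 0.2, intensity_range = c(235, 250),
                                 orientations = c(0, 90), fraction_recalcitrant = 0.45)
scen <- degradation_scenario("dissolve", dissolve_hazard_per_h = 0.172,
                             sugar_max_yield_pct = 37)
imaging <- imaging_config(height_px = 256, width_px = 256, n_replicates = 3,
                          time_points_h = c(0, 0.25, 0.5, 1, 2, 3, 5, 7),
                          background_amplitude = 8, background_scale_px = 600,
                          noise_sd = 2, allow_overlap = FALSE, seed = 42)

sim  <- simulate_time_lapse(spec, scen, imaging)
meas <- measure_time_lapse(sim$frames, sim$times_h)
round(meas$measurements, 3)
#>   time_h relative_particle_number mean_size_um n_replicates
#> 1   0.00                    1.000      128.966            3
#> 2   0.25                    0.994      128.721            3
#> 3   0.50                    0.976      129.655            3
#> 4   1.00                    0.915      128.872            3
#> 5   2.00                    0.885      128.889            3
#> 6   3.00                    0.816      126.124            3
#> 7   5.00                    0.763      129.736            3
#> 8   7.00                    0.725      131.241            3
```

The dissolution fingerprint is already visible: the relative particle number
falls by ~28% while the mean size stays flat (whole particles vanish, the
survivors' size distribution is untouched). Fitting the number series:

```r
number <- kinetic_series(meas$measurements$time_h,
                         meas$measurements$relative_particle_number,
                         kind = "particle_number")
fit_exponential(number, "auto")
#> <exponential_fit> 1 component(s), decreasing
#>   A = 0.3385, k = 0.2589 1/h, baseline = 1.008
#>   t1/2 = 2.678 h, rss = 0.0007101, R2 = 0.9911
```

so half of the total particle loss is reached after ~2.7 h. On the NMR side,
invert a three-population CPMG decay at 60% moisture and quantify the water
held in enzyme-sized pores:

```r
truth <- ground_truth_t2(data.frame(t2_ms = c(1, 11, 300), log_sd = 0,
                                    weight = c(1, 1, 1) / 3),
                         total_water_content = 60, moisture_content = 60)
decay <- simulate_cpmg(truth, echo_spacing_ms = 0.2, n_echoes = 4096,
                       noise_sd = 0.05, seed = 42)
spectrum <- ilt(decay, lambda = "auto")
spectrum
#> <t2_spectrum> 200 grid points, lambda = 0.524, 3 component(s)
#>   peak_t2_ms        p2
#> 1   1.030302 0.3310889
#> 2  11.043283 0.3337254
#> 3 300.047541 0.3351857
water_in_pore_band(spectrum, default_pore_calibration())
#> ~20.0  (% w/w: only the 11 ms population maps into the 5-15 nm band)
```

All three true populations are recovered with proportions within ~0.2% of
the 1/3–1/3–1/3 truth, and the 5–15 nm band holds one third of the 60% w/w
water, as constructed.

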