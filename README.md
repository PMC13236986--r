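# jetcurve

Detection of the Northern Hemisphere westerly jet axis from gridded
upper-level zonal-wind fields, a streamline-curvature indicator suite for
quantifying how the jet bends, and the statistical diagnostics that connect
jet curvature to terrestrial gross primary productivity (GPP) and to
individual anthropogenic forcings.

## Who this is for

Climate and ecosystem scientists who want a *regional*, signed measure of
jet-stream waviness. Hemispheric waviness indices tell you the flow got
wavier; they cannot tell you that the flow over one sector reversed from a
southward (cyclonic) trough to a northward (anticyclonic) ridge while a
neighbouring sector did the opposite — which is exactly the kind of change
that reorganises surface heat, precipitation, and hence vegetation
productivity, along whole longitude bands.

## The method

1. **Axis detection.** Daily 200 hPa zonal-wind fields over 0–90°N are
   filtered with grayscale morphology: a *closing* (dilation–erosion) that
   consolidates the jet core, then an *opening* (erosion–dilation) that
   removes isolated high-wind anomalies smaller than the structuring
   element. The jet axis is the latitude of maximum filtered wind at each
   longitude, smoothed with a longitude-periodic ~1000 km moving average.

2. **Curvature.** With the axis as a polyline y(x) (latitude vs longitude,
   degrees), the signed local curvature at each longitude is

   κ(x) = − y″ / (1 + y′²)^{3/2}   [degree⁻¹]

   (central differences, periodic in longitude). The sign convention is
   ridge-positive: a northward anticyclonic bulge has κ > 0, a southward
   cyclonic trough κ < 0. |κ| measures bending regardless of direction, and
   the hemispheric *overall curvature* is the RMS √(Σκᵢ²/N) across all
   longitudes. Seasonal (JJA) means, eight-sector aggregates
   (WE, EE, CA, EA, PA, WN, CN, EN), trends, and epoch anomalies build on
   these.

3. **Productivity diagnostics.** Per-cell (detrended) correlation and
   regression maps of GPP against the curvature index with 95% significance
   masks, stratification of |r| by managed vs natural land use, and binned
   response curves with a two-segment hinge fit for threshold behaviour
   (e.g. GPP rising with maximum temperature up to an optimum, then
   flattening).

4. **Attribution.** For single-forcing large ensembles (ALL and XGHG /
   XAER / XBMB, where one forcing is held fixed), the contribution of
   forcing F to a change C is

   ΔC_F = (C_ALL − C_XF) / C_ALL × 100%

   with C the ensemble-mean trend × period span (or an epoch difference),
   and percentile bootstrap confidence intervals over ensemble members.
   Contributions are reported signed and unclamped.

A synthetic-data module generates wind fields around a known meandering
axis, productivity fields with a known coupled-cell mask, and additive
forcing ensembles with prescribed shares — so every stage is testable
against ground truth without downloading any archive.

## Worked example

```r
library(jetcurve)

axis_spec <- jet_axis_spec(45, list(c(5, 6, 0)))       # 5 deg meander, wavenumber 6
field <- generate_wind_field(axis_spec,
           wind_field_spec(noise_sd = 5, seed = 1,     # SNR 5
                           spurious_patch_rate = 4, patch_sides = 2L))
axis <- detect_axis(field, structuring_element(3, 3, "disk"))
profile <- pointwise_curvature(axis)

overall_curvature(profile)
#>   time      value anomaly
#> 1    1 0.06140959       0

round(sector_mean(profile)[1, ], 4)
#>      WE      EE      CA      EA      PA      WN      CN      EN
#> -0.0032 -0.0065  0.0028 -0.0155  0.0083 -0.0113 -0.0028  0.0163

mean(abs(axis$lat - attr(field, "true_axis")) <= 2.5)  # axis recovery
#> [1] 1
```

The overall curvature 0.0614 degree⁻¹ is the RMS waviness of the detected
axis; the sector means show which sectors bend northward (positive, e.g. PA
and EN here) versus southward (negative, e.g. EA); and despite cell noise at
a fifth of the jet peak and four spurious high-wind patches, the detected
smoothed axis is within one grid cell of the true axis at every longitude —
the patches are removed by the opening because they are smaller than the
structuring element.

Attribution on a synthetic ensemble with prescribed GHG:AER:BMB shares
70:20:10:

```r
tt <- seq(0, 1, length.out = 51)
ens <- generate_ensemble(ensemble_spec(
  response_ghg = 1.4 * tt, response_aer = 0.4 * tt, response_bmb = 0.2 * tt,
  internal_sd = 0.2, years = 2030:2080, seed = 7))
forcing_contribution(ens, seed = 1)
#> <attribution_result> trend_change over 2030-2080 (95% bootstrap CI)
#>  forcing contribution  lower upper
#>      GHG       68.733 66.439 71.35
#>      AER       21.611 19.467 23.73
#>      BMB        9.604  6.941 12.41
```

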