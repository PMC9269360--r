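# bloomstage

Phytoplankton bloom stage estimation from satellite chlorophyll-a phenology
and shipboard pheophytin proportions.

## The problem

Optical satellites track surface chlorophyll-a well enough to describe the
seasonal *shape* of a phytoplankton bloom, but they see nothing under clouds,
under ice, or below the surface. Shipboard pigment samples see the whole water
column but only on the day the ship is there. `bloomstage` connects the two:
it uses the satellite time series to decide whether a bloom was **growing**
(Early Bloom, EB), **past its peak** (Post Bloom, PB), or absent (No Bloom,
NB) on the day of field sampling, and then calibrates a shipboard pigment
index so that bloom stage can be read off a bottle sample alone.

The index is the **pheophytin proportion**

    p = Pheo / (Chl-a + Pheo)

where pheophytin is the degraded, oxidized product of chlorophyll-a that
accumulates as a bloom ages and is grazed. A growing bloom is
pheophytin-poor; a mature one is pheophytin-rich. The package's calibration
scans every integer percentage threshold T in 0–100, classifies each sampled
station-year as EB (`p < T/100`) or PB (`p >= T/100`), scores the result
against the satellite stages with a remote-sensing error matrix (overall
accuracy, omission/commission errors), and selects the best T.

The satellite side follows standard ocean-color phenology practice: per
station-year series are ice-masked (>15% sea-ice concentration),
quality-controlled (>=6 observations, no gap over 25 days, >=3 observations
in the DOY 174–219 sampling window), smoothed with a tricube locally weighted
linear fit, interpolated to a daily curve, and segmented into bloom cycles
with start/peak/end days (t1, t2, t3; a cycle must rise >=0.5 mg/m3). The
stage at sampling day d is

    NB :  d < t1  or  d > t3
    EB :  t1 <= d <= t2
    PB :  t2 <  d <= t3

Sea-ice helpers classify station-years as high or low ice two ways — by the
breakup date (first 2-day run below 15% concentration) against a per-station
at-most-one-change (AMOC) changepoint threshold, and by a >5-day zero-ice run
during March 1 – May 1 — and Welch's t-test compares pheophytin proportions
between the ice regimes.

A synthetic-data module generates cloud-thinned chlorophyll series, seasonal
ice-decline curves, and stage-dependent pigment profiles with known truth, so
the entire pipeline is testable without any satellite downloads.

## Worked example

Generate a full synthetic study (13 stations x 7 Julys, low-ice regime in the
final two years), calibrate the threshold, and compare ice regimes:

```r
library(bloomstage)

study <- gen_full_study(seed = 42)
cal   <- run_calibration(study$chl, study$ice, study$pigments)
cal
#> <calibration_report> 91 station-years staged, 58 matched pairs
#> selected threshold 26% (overall accuracy 94.8%)
cal$error_matrix
#>      satellite
#> field EB PB
#>    EB  9  2
#>    PB  1 46
#> overall accuracy 94.8% (55 consistent / 3 inconsistent)

cmp <- run_ice_comparison(study$pigments, study$ice)
cmp
#> <ice_comparison_report> 91 ice station-years, 91 with pigments
#>              level        scheme n_low n_high mean_low mean_high     t        p
#> 1          surface concentration    26     65    0.310     0.455 -4.68 4.76e-05
#> 2 depth_integrated concentration    26     65    0.398     0.548 -4.72 4.17e-05
#> 3          surface       breakup    26     65    0.310     0.455 -4.68 4.76e-05
#> 4 depth_integrated       breakup    26     65    0.398     0.548 -4.72 4.17e-05
```

Reading the output: of 91 station-years, 58 had both a usable satellite
EB/PB stage and a surface pigment sample; the scan selected a 26% threshold
(the generator's stage regimes sit just below and above a 0.28 boundary, and
ties resolve to the smallest equally accurate threshold). The four-way
comparison shows low-ice years carrying systematically *lower* pheophytin
proportions — July sampling catches their delayed blooms still growing —
significant under both binning schemes at both depth levels.

Real data enter through three CSVs (`read_chl_series`,
`read_ice_series`, `read_pigment_samples`; headers
`station_id,year,doy,chl_mg_m3`, `station_id,year,doy,ice_pct`,
`station_id,year,doy,depth_m,chl_ug_L,pheo_ug_L`), and every result table
writes back to CSV with `write_calibration_report` / `write_ice_comparison`.

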