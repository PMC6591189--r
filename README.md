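# lvpump

Single-beat estimation of left-ventricular (LV) pumping mechanics in R.

Cardiac contractility and the resistive behaviour of the ejecting
ventricle are captured by the elastance–resistance pump model through two
parameters: the **maximal systolic elastance** `E_max` (mmHg/mL) and the
**theoretical maximum flow** `Q_max` (mL/s).  Fitting that model classically
needs simultaneously recorded LV pressure, aortic flow, and an
occlusion-measured isovolumic pressure — the last being impossible in
patients.  `lvpump` implements a single-beat technique that needs only a
**measured LV pressure pulse and the cardiac output**:

- the isovolumic pressure curve `P_iso(t) = P_d + (P_idmax/2)[1 − cos(ω(t−t_ed)+C)]`
  is estimated from the ejecting beat by non-linear least squares, giving
  its peak `P_isomax = P_d + P_idmax`;
- an assumed **triangular aortic flow** `Q^tri` is located from the
  15-harmonic reconstruction of the fourth time derivative of the LV
  pressure and calibrated so its area equals the stroke volume
  `SV = CO·60/HR`;
- the elastance–resistance model
  `P(t) = P_iso(t)·[1 − V_ej(t)/V_eed − Q(t)/Q_max]`
  is fitted to the measured pressure over early systole
  (`t_ej < t < t_pisomax`), and
  `E_max = P_isomax/V_eed`, `R_max = P_isomax/Q_max`;
- the pressure–ejected-volume loop additionally yields the tangent
  end-systolic elastance `E_es` (slope of the line from `(0, P_isomax)`
  touching the loop).

The package is aimed at cardiovascular physiologists and biomedical
engineers working with pressure–volume data at small-mammal scale.  It
also contains a mechanistic beat simulator (time-varying elastance +
internal resistance + three-element windkessel) with exact ground truth,
and a validation harness (linear regression and Bland–Altman agreement)
comparing pressure-only estimates against measured-flow estimates on
synthetic cohorts.

## Worked example

A bundled synthetic record (healthy-rat scale, five beats of LV pressure
with ECG and a measured aortic flow channel, 1 kHz, 1 % pressure noise;
generated by the package's own simulator) is analysed with its known
cardiac output and heart rate:

```r
library(lvpump)
rec <- system.file("extdata", "synthetic_nc_rat.csv", package = "lvpump")
an <- analyze_record(rec, CO = 2.17, HR = 398)
an
#> <lv_analysis>
#> <lv_isofit> P_isomax = 245.2 mmHg (P_d = 14.4, P_idmax = 230.9), omega = 74.93 rad/s
#>   t_pisomax = 0.0376 s, rms residual = 4.21 mmHg (10 + 7 pts)
#> <lv_triflow> onset 0.005 s, peak 0.017 s, end 0.06 s; q_peak = 11.9 mL/s, SV = 0.3271 mL
#> -- triQ --
#> <lv_es> E_es = 431.6 mmHg/mL (triangular flow); equilibrium point (0.3249 mL, 105 mmHg)
#> <lv_erfit> (triangular flow) Q_max = 37.94 mL/s, V_eed = 0.5771 mL
#>   E_max = 424.9 mmHg/mL, R_max = 6.462 mmHg s/mL; r2 = 0.9667, SEE = 2.64% (n = 32)
#> -- mQ --
#> <lv_es> E_es = 440 mmHg/mL (measured flow); equilibrium point (0.3226 mL, 103.3 mmHg)
#> <lv_erfit> (measured flow) Q_max = 31.1 mL/s, V_eed = 0.5339 mL
#>   E_max = 459.3 mmHg/mL, R_max = 7.885 mmHg s/mL; r2 = 0.9384, SEE = 3.32% (n = 31)
```

Reading the output: the five beats were ensemble-averaged on the R wave;
the estimated peak isovolumic pressure is 245 mmHg (the record was
simulated with a true valve-disabled peak near 263 mmHg); the triangular
flow spans 5–60 ms of the beat and is calibrated to a stroke volume of
0.327 mL.  The pressure-only route (`triQ`) then gives
`E_max ≈ 425 mmHg/mL` and `Q_max ≈ 38 mL/s` against simulated truths of
450 and 38, and the measured-flow route (`mQ`) gives 459 and 31; the
tangent `E_es` (432 and 440) agrees with `E_max` within a few percent, and
both model fits track the measured pressure closely (r² ≈ 0.94–0.97).
`result_json(an)` serialises everything (with units) to the JSON result
schema.

Ground truth for your own experiments comes from the simulator:

```r
sb <- simulate_beat_modeA(sim_params("NC", noise_sd_pct = 1, seed = 7))
an <- analyze_beat(sb$beat, CO = sb$CO, HR = sb$HR, flow = sb$flow)
coh <- generate_cohort(50, seed = 11)     # mixed presets, truth manifest
rep <- run_validation(coh)                # triQ-vs-mQ regression + Bland-Altman
```

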