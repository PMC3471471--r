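# File schemas

All delimited files are comma-separated UTF-8 with a header row.

## Treatment cohort records (input to `deltas_from_record()` / `fit_dose_curves()`)

| column     | type    | units  | meaning                                  |
|------------|---------|--------|------------------------------------------|
| drug       | string  |        | drug identifier (e.g. enalapril)         |
| dose_mg_d  | numeric | mg/day | daily dose                               |
| sbp_pre    | numeric | mmHg   | systolic pressure before treatment       |
| dbp_pre    | numeric | mmHg   | diastolic pressure before treatment      |
| sbp_post   | numeric | mmHg   | systolic pressure after treatment        |
| dbp_post   | numeric | mmHg   | diastolic pressure after treatment       |
| n          | integer |        | group size (optional; least-squares weight) |

## Patient records (input to `predict_patient()`)

| column | type    | units     | meaning                                   |
|--------|---------|-----------|-------------------------------------------|
| id     | string  |           | patient identifier                        |
| sbp    | numeric | mmHg      | measured systolic pressure                |
| dbp    | numeric | mmHg      | measured diastolic pressure               |
| drug   | string  |           | optional; drug to simulate                |
| dose   | numeric | mg/day    | optional; 0 = no treatment                |
| ef     | numeric | %         | optional supplement: ejection fraction    |
| sw     | numeric | J/beat    | optional supplement: stroke work          |
| hr     | numeric | beats/min | optional heart-rate override              |

## Hemodynamic profiles (input to `score_cii()`)

Columns `MAP` (mmHg), `PP` (mmHg), `HR` (beats/min), `CO` (L/min), `SV`
(mL), `EF` (%), `SW` (J/beat); `score_cii()` appends `cii`.

## JSON sidecars

* Pressure surface: `windkesselrc/pressure_surface/v1` - grid spec, mode,
  physics, row-major values (see `write_surface()`).
* Dose-effect curve: `windkesselrc/dose_effect_curve/v1` - drug, quantity,
  `E_max`, `d50`, `fit_rss`, `n_points` (see `write_dose_curve()`).

## Packaged fixtures

* `acei_cohort_baselines.csv`: published baseline characteristics of eight
  ACEI-treated heart-failure cohorts (provenance column cites the trials).
* `acei_reference_profiles.csv`: the worked enalapril/lisinopril 20 mg/d
  example - baseline, simulated and measured columns; `NA` where the trials
  did not report a value.
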