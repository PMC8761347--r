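Place transcribed NZ case-study input tables here to reproduce the published
cohort results (60-64 year-old Maori females, 2011, 20 annual cycles):

  aggregate_rates.csv          age,quantity,value   (mortality + yld rows)
  acmr_ratios.csv              stratum,age_band_start,age_band_end,ratio
  morb_ratios.csv              stratum,age_band_start,age_band_end,ratio
  chd_inputs.csv               age,quantity,value   (incidence + fatality rows)
  chd_inc_ratios.csv           stratum,age_band_start,age_band_end,ratio
  chd_fat_ratios.csv           stratum,age_band_start,age_band_end,ratio
  chd_prev_ratios.csv          stratum,ratio
  stroke_inputs.csv            age,quantity,value
  stroke_inc_ratios.csv        stratum,age_band_start,age_band_end,ratio
  stroke_fat_ratios.csv        stratum,age_band_start,age_band_end,ratio
  stroke_prev_ratios.csv       stratum,ratio
  exposure_categories.csv      category,proportion,mean_exposure
  rr_per_unit.csv              disease,rr_per_unit
  config_intervention_A.yaml / _B.yaml / _C.yaml

These inputs are published as supplementary material to the study this
method reproduces and are not redistributed with the package. Header-only
templates for each dialect are under ../templates/.
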