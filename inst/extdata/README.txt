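Bundled reference tables (plain text, comma-separated)
------------------------------------------------------

citrus_measurement_days.csv
  Summary of the 17 measurement days of the two-season citrus gas-exchange
  campaign (dates, time windows, per-day observation counts, weather,
  average soil moisture %). The counts sum to 1852 (1001 in 2021, 851 in
  2022) and are the default per-day shape of the synthetic generator.

citrus_daily_lambda.csv
  Daily representative (trimmed-median) marginal water cost of carbon gain
  lambda (mol H2O per mol CO2) per measurement day, for the co-limited,
  Rubisco-limited (vc) and RuBP-regeneration-limited (vj) pools. Blank
  cells mean the pool was empty that day. The overall medians of these
  pools (1787.10 / 1478.51 / 2703.65) are the package's characteristic
  lambda defaults.

citrus_aci_parameters.csv
  Per-curve calibration results of the five A-ci response curves (leaf
  temperature, fitted Km and gamma*, and 25 degC-normalised Vcmax25,
  Jmax25, Rd25). Column averages of the three rates (43.21, 75.56, 1.77)
  are the package's default species parameters. Km and gamma* were fitted
  per curve (free mode); they do not coincide with the temperature-response
  functions evaluated at Tl.

Values use '.' decimal; thousands separators appear quoted ("1,787.10")
and are stripped by the package readers.
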