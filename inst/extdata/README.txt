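External data drop-in directory.

landing_observations_deposited.csv — the raw field table of landing
attempts (8623 records) is not redistributed with this package. To run
the observational reproduction checks in tests/testthat/test-acceptance.R,
place the deposited CSV here under that name, using the package column
schema (colony, day, species, ledge, height, wind, turbulence, success)
or passing a column_map to read_observations()/
analyse_deposited_observations().
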