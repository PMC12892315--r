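# shared fixtures, built once per test run
fx <- generate_fixture(1)                          # calibrated, uncertain
fx_point <- generate_fixture(fixture_spec(1, noise_level = 0))  # degenerate

fin_default <- financial_params()

# independent annuity/CRF arithmetic used as oracle throughout
oracle_annuity <- function(r, T) if (r == 0) T else (1 - (1 + r)^(-T)) / r
oracle_crf <- function(r, T) r * (1 + r)^T / ((1 + r)^T - 1)
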