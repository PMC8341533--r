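# emmod pipeline configuration (flat key = value; '#' starts a comment)
#
# Inputs: CSV files with a header row, a 'date' column (YYYY-MM or
# YYYY-MM-DD) and a 'value' column. 'response' may list several station
# CSVs separated by commas; stations are averaged (monthly binning) and
# spline-regularized onto the driver's monthly grid.

driver = driver.csv
response = L001.csv, L003.csv, L004.csv, L007.csv, L008.csv
out_dir = emm_out

# state-space reconstruction; E left unset selects the dimension by
# univariate forecast skill
# E = 3
tau = 1
tp = 0
exclusion_radius = 12     # samples (months); Theiler window

# band selection: auto (classify IMFs by Hilbert mean period) or explicit
band_mode = auto

# CCM sweep and significance testing
subsamples = 100
n_surrogates = 1000
seed = 1
standardize_for_ccm = TRUE
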