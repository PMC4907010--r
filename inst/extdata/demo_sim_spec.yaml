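# Demo simulation: four weeks of synthetic ED visits with the default
# diurnal profile, over-dispersed arrivals and routine-registration
# missingness of the surrogate timestamps.
period_start: "2013-01-01 00:00"
period_end: "2013-01-29 00:00"
seed: 42
interval_width_min: 30
daily_mean: {weekday: 114, weekend: 115}
count_model: negative_binomial
dispersion_k: 5
miss_prob: {triage: 0.718, first_ews: 0.879, last_ews: 0.906}
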