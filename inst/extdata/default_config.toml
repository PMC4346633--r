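[imaging]
generation_offset = 1
n_founders = 40
imaging_window = [3960, 5400]
frame_interval = [3, 4]
max_depth = 4
activation_lag_min = 1440

[distributions]
gen_mean_h = [13.4, 14.3, 14.3]
gen_sd_h = [5.4, 4.4, 4.4]

[heritability]
share_family = 0.2
share_drift = 0.4
share_division = 0.5
share_individual = 0.2
drift_center = 1.5

[slow_state]
onset_generation = 8
p_on = 0.25
p_stay = 0.8
p_arrest = 0.35
meanlog = 7.49554194388426
sdlog = 0.35

[reporter]
d_dn_min = 60
g1_frac_fast = 0.25
g1_frac_slow = 0.7
plateau = 1000
ko_high_level = 2500
rise_min = 10
decay_min = 3
noise_cv = 0.05
background = 20

[ctv]
i0 = 10000
cv = 0.15
floor_generation = 9

[brdu]
s_frac = 0.6

[phenotype]
death_prob = 0

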