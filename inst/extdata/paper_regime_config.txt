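# midpass synthetic cohort configuration
n_patients: 50
baseline_mean: nrs=6.5, prwhe_pain=34.2, prwhe_function=30.0
baseline_sd: nrs=1.7, prwhe_pain=6.8, prwhe_function=7.9
baseline_cor: 0.35
recovery_curve: post_splint_6wk=0.10, m3=0.25, m6=0.35, m9=0.40, m12=0.45
patient_sd: 0.2
occasion_sd: 0.1
noise_sd: nrs=1, prwhe_pain=3, prwhe_function=3
grc_thresholds: -5.5, -1.5, 2.5, 3.5
anchor_noise_sd: 0.8
pass_location: 2.5
pass_scale: 0.55
pass_nrs_weight: 0.6
missing_rate: 0
items: false
seed: 1
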