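# Example pipeline configuration for run_pipeline(): a 60-month study
# window with interruptions opening months 29 and 50, simulated at a
# reduced monthly cohort size for a quick run.
interruptions: [29, 50]
n_months: 60
patients_per_month: 200
seed: 42
alpha: 0.05
estimator: auto
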