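# Default generating recipe: 50 clusters of 100 subjects, one standard-normal
# predictor with coefficient 1.5, ICC 0.20 on the latent scale, and the
# intercept solved for a 50% marginal outcome prevalence.
J: 50
n_j: 100
beta1: 1.5
icc: 0.20
target_prevalence: 0.5
seed: 1
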