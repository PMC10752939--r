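# Calibration constants of the factorial synthetic benchmark generator.
# effect_size: mean shift (+/-) of every informative gene, per feature level.
# noise_gene_sd: within-cell SD of the unstructured noise-gene block; fixed
#   across the sigma sweep, so that high-variance noise genes compete with
#   the signal blocks for unsupervised variance capture at every noise level.
effect_size: 1.2
noise_gene_sd: 15.5
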