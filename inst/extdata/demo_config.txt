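# demo configuration for `gametephase simulate|run --config`
# key = value pairs mirroring sim_config(); unknown keys are rejected
n_chromosomes = 2
chrom_length = 100000
snp_rate = 0.002
n_cells = 12
crossover_lambda = 1
genotype_error = 0.01
missing_rate_target = 0.4
het_call_rate = 0.01
mda_window = 10000
mda_gamma_shape = 0.8
read_length = 100
mean_depth = 4
seed = 7
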