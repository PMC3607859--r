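# Demonstration pipeline configuration: a 10 x 10 simulated lattice with
# the default reference covariate effects, short two-chain MCMC runs.
out_dir: results/demo
seed: 20070101
simulation:
  n_rows: 10
  n_cols: 10
  contiguity: rook
  n_provinces: 4
mcmc:
  n_chains: 2
  n_burnin: 1500
  n_retain: 2500
hotspot_threshold: 0.9
significance_prob: 0.95
inequality_quantile: 0.6667
determinants:
  - comp_no_water
  - comp_no_toilet
  - comp_no_refuse
  - comp_no_electricity
  - comp_no_schooling
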