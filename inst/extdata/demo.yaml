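# Default end-to-end demo configuration: the Le Mans-style pool of eight
# presumed-homozygous Rose-combed birds (4 R1 / 9 R2 / 3 r chromosomes),
# sequenced as a 3.9 kb mate-pair library at ~1x coverage on the 1/100-scale
# toy reference.
seed: 1
scale_div: 100
ref_length: 300000
gc: 0.42
pool:
  R1: 4
  R2: 9
  r: 3
mu: 3900
sigma: 390
read_len: 50
coverage: 1
window: 1500
min_frac: 0.25
cluster_radius: 1000
min_pairs: 4
sd_mult: 10
cohort_n: 200
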