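# Synthetic bulk-segregant experiment: F2 population segregating 3:1 for a
# single recessive locus, 30-plant phenotype-selected bulks, ~25x pooled
# whole-genome sequencing on a reduced 3 x 10 Mb genome.
genome:
  chromosomes:
    - {name: A01, length: 10000000}
    - {name: A02, length: 10000000}
    - {name: A03, length: 10000000}
  recomb_rate: 2.5        # cM per Mb
cross:
  kind: F2
  population_size: 927
causal:
  chromosome: A03
  position: 2500000
bulks:
  bulk_size: 30
sequencing:
  mean_depth: 25
  error_rate: 0.001
  depth_model: poisson
seed: 1
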