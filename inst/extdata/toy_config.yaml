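# Bundled toy pipeline configuration: a small repeat-rich chromosome with a
# telomeric array of 3 families, a 2-family centromeric island, 3 scattered
# background complex repeats and 3 satellite tracts; two IP replicates
# enriched at the telomeric families against two no-tag control replicates.
genome:
  chrom_length: 60000
  telomeric_families: {telA: 10, telB: 10, telC: 10}
  telomeric_consensus_length: 600
  centromeric_families: {cenA: 8, cenB: 8}
  centromeric_consensus_length: 300
  background_families: {bgA: 3, bgB: 3, bgC: 3}
  background_consensus_length: 500
  simple_repeats: {AACAC: 400, AATAT: 250, AG: 300}
  truncation_prob: 0.7
  mutation_rate: 0.02
samples:
  - sample_label: IP
    target_name: capping
    replicate_id: rep1
    n_pairs: 5000
    weights: {telA: 10, telB: 10, telC: 10}
  - sample_label: IP
    target_name: capping
    replicate_id: rep2
    n_pairs: 5000
    weights: {telA: 10, telB: 10, telC: 10}
  - sample_label: no_tag
    target_name: none
    replicate_id: rep1
    n_pairs: 5000
  - sample_label: no_tag
    target_name: none
    replicate_id: rep2
    n_pairs: 5000
params:
  theta: 0.2
  eps: 0.01
  mapq: 10
  bin_size: 100
  k_max: 20
  min_copies: 3
  min_fraction: 0.5
  read_length: 50
  fragment_length_mean: 200
  fragment_length_sd: 40
  error_rate: 0.001
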