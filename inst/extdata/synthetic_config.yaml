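genome: synthetic_genome.fa
coords: synthetic_coords.tsv
cds: synthetic_cds.fa
proteins: synthetic_proteins.fa
primers: synthetic_primers.tsv
training_set: synthetic_training_set.tsv
ct_table: synthetic_ct.tsv
seed: 1
params:
  top_k: 1
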