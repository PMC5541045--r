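# Example genome specification for the `synth` subcommand.
length_bp: 80000
gc_content: 0.45
decoy_gene_count: 4
contig: example_contig
seed: 1
loci:
  - subtype: III-B/C
    fusion_class: RT-Cas1
    clade: clade1
    array:
      n_repeats: 6
      leader_at_enrichment: 0.2
      terminal_repeat_mutations: 3
      orientation: forward
  - subtype: III-A/D
    fusion_class: Cas6-RT-Cas1
    clade: clade2
    array:
      n_repeats: 5
      orientation: reverse
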