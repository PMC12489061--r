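# Toy genome used by the `reproduce-toy` subcommand and the test suite.
# Two chromosomes; one dispersed and one tandem paralog family plus a
# diverged family that falls below the 0.7 similarity threshold.
seed: 1
chromosomes:
  chrI: 60000
  chrII: 40000
families:
  - n_copies: 3
    gene_length: 1200
    sub_rate: 0.02
    indel_rate: 0.001
    placement: dispersed
  - n_copies: 3
    gene_length: 800
    sub_rate: 0.05
    indel_rate: 0
    placement: tandem
    spacer: 150
  - n_copies: 2
    gene_length: 1000
    sub_rate: 0.35
    indel_rate: 0.01
    placement: dispersed
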