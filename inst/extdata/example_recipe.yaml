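# Example simulation recipe: a three-virus co-infection library modeled on
# the AEFV/MERV/SHTV system. AEFV- and SHTV-like genomes receive only
# vsiRNAs plus positive-strand degradation reads (no piRNA signature);
# the MERV-like rhabdovirus receives vsiRNAs with a 5'-UTR hotspot on the
# negative strand plus canonical ping-pong vpiRNAs over its structural genes.
seed: 101
sequencing_error_rate: 0.005
adapter: AGATCGGAAGAGC
constant_quality: 37
host_length: 10000
genomes:
  - name: AEFV
    length: 11064
    sense: positive
    genes:
      - {label: 5UTR, start: 0, end: 95}
      - {label: polyprotein, start: 95, end: 10300}
      - {label: 3UTR, start: 10300, end: 11064}
  - name: MERV
    length: 11000
    sense: negative
    genes:
      - {label: 5UTR, start: 0, end: 130}
      - {label: structural_NPMG, start: 130, end: 4162}
      - {label: L, start: 4200, end: 10900}
  - name: SHTV
    length: 5500
    sense: positive
classes:
  - genome: AEFV
    class_label: vsiRNA
    count: 3000
    strand_fraction_positive: 0.55
    hotspots:
      - {start: 10300, end: 11064, weight: 10}
  - genome: AEFV
    class_label: degradation
    count: 600
    strand_fraction_positive: 0.9
  - genome: MERV
    class_label: vsiRNA
    count: 2500
    strand_fraction_positive: 0.45
    hotspots:
      - {start: 0, end: 130, weight: 10}
  - genome: MERV
    class_label: vpiRNA_primary
    count: 900
    strand_fraction_positive: 1.0
    p_1U: 0.9
    hotspots:
      - {start: 130, end: 4162, weight: 8}
  - genome: MERV
    class_label: vpiRNA_secondary
    count: 600
    strand_fraction_positive: 0.0
    pingpong_fraction: 0.5
  - genome: SHTV
    class_label: vsiRNA
    count: 2000
    strand_fraction_positive: 0.5
  - genome: SHTV
    class_label: degradation
    count: 200
    strand_fraction_positive: 0.85
  - genome: host
    class_label: background
    count: 4000
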