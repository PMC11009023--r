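seqspec_version: 0.3.0
assay_id: indrops-like
name: synthetic variable-length barcode scRNA-seq
description: '8-12 bp first-round barcode: downstream offsets vary per molecule'
modalities:
- rna
library_spec:
- region_id: rna
  region_type: rna
  name: rna
  sequence_type: joined
  sequence: NNNNNNNNNNNNXXXXXXNNNNNNNNXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXX
  min_len: 72
  max_len: 76
  onlist: ~
  regions:
  - region_id: read1
    region_type: fastq
    name: read1
    sequence_type: joined
    sequence: NNNNNNNNNNNNXXXXXXNNNNNNNN
    min_len: 22
    max_len: 26
    onlist: ~
    regions:
    - region_id: barcode1
      region_type: barcode
      name: round-1 barcode (variable)
      sequence_type: onlist
      sequence: ''
      min_len: 8
      max_len: 12
      onlist:
        filename: barcode1.txt
        location: local
      regions: []
    - region_id: umi
      region_type: umi
      name: umi
      sequence_type: random
      sequence: ''
      min_len: 6
      max_len: 6
      onlist: ~
      regions: []
    - region_id: barcode2
      region_type: barcode
      name: round-2 barcode
      sequence_type: onlist
      sequence: ''
      min_len: 8
      max_len: 8
      onlist:
        filename: barcode2.txt
        location: local
      regions: []
  - region_id: read2
    region_type: fastq
    name: read2
    sequence_type: joined
    sequence: XXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXX
    min_len: 50
    max_len: 50
    onlist: ~
    regions:
    - region_id: cdna
      region_type: cdna
      name: cdna
      sequence_type: random
      sequence: ''
      min_len: 50
      max_len: 50
      onlist: ~
      regions: []
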