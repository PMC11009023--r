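seqspec_version: 0.3.0
assay_id: tenx-like
name: synthetic droplet scRNA-seq (fixed geometry)
description: 16 bp onlist barcode + 12 bp UMI in read 1, cDNA in read 2
modalities:
- rna
library_spec:
- region_id: rna
  region_type: rna
  name: RNA modality
  sequence_type: joined
  sequence: NNNNNNNNNNNNNNNNXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXX
  min_len: 118
  max_len: 118
  onlist: ~
  regions:
  - region_id: read1
    region_type: fastq
    name: Read 1
    sequence_type: joined
    sequence: NNNNNNNNNNNNNNNNXXXXXXXXXXXX
    min_len: 28
    max_len: 28
    onlist: ~
    regions:
    - region_id: barcode
      region_type: barcode
      name: cell barcode
      sequence_type: onlist
      sequence: ''
      min_len: 16
      max_len: 16
      onlist:
        filename: barcodes.txt
        location: local
      regions: []
    - region_id: umi
      region_type: umi
      name: molecular identifier
      sequence_type: random
      sequence: ''
      min_len: 12
      max_len: 12
      onlist: ~
      regions: []
  - region_id: read2
    region_type: fastq
    name: Read 2
    sequence_type: joined
    sequence: XXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXX
    min_len: 90
    max_len: 90
    onlist: ~
    regions:
    - region_id: cdna
      region_type: cdna
      name: complementary DNA
      sequence_type: random
      sequence: ''
      min_len: 90
      max_len: 90
      onlist: ~
      regions: []
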