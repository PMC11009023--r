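seqspec_version: 0.3.0
assay_id: shareseq-like
name: synthetic two-modality split-pool assay
description: three 8 bp split-pool barcode rounds shared by rna and atac
modalities:
- rna
- atac
library_spec:
- region_id: rna
  region_type: rna
  name: rna
  sequence_type: joined
  sequence: XXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXNNNNNNNNGTGTCANNNNNNNNGCTTCTNNNNNNNNXXXXXXXXXX
  min_len: 96
  max_len: 96
  onlist: ~
  regions:
  - region_id: rna-read1
    region_type: fastq
    name: rna-read1
    sequence_type: joined
    sequence: XXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXX
    min_len: 50
    max_len: 50
    onlist: ~
    regions:
    - region_id: rna-cdna
      region_type: cdna
      name: rna-cdna
      sequence_type: random
      sequence: ''
      min_len: 50
      max_len: 50
      onlist: ~
      regions: []
  - region_id: rna-read2
    region_type: fastq
    name: rna-read2
    sequence_type: joined
    sequence: NNNNNNNNGTGTCANNNNNNNNGCTTCTNNNNNNNNXXXXXXXXXX
    min_len: 46
    max_len: 46
    onlist: ~
    regions:
    - region_id: rna-bc1
      region_type: barcode
      name: rna-bc1
      sequence_type: onlist
      sequence: ''
      min_len: 8
      max_len: 8
      onlist:
        filename: round1.txt
        location: local
      regions: []
    - region_id: rna-linker1
      region_type: linker
      name: rna-linker1
      sequence_type: fixed
      sequence: GTGTCA
      min_len: 6
      max_len: 6
      onlist: ~
      regions: []
    - region_id: rna-bc2
      region_type: barcode
      name: rna-bc2
      sequence_type: onlist
      sequence: ''
      min_len: 8
      max_len: 8
      onlist:
        filename: round2.txt
        location: local
      regions: []
    - region_id: rna-linker2
      region_type: linker
      name: rna-linker2
      sequence_type: fixed
      sequence: GCTTCT
      min_len: 6
      max_len: 6
      onlist: ~
      regions: []
    - region_id: rna-bc3
      region_type: barcode
      name: rna-bc3
      sequence_type: onlist
      sequence: ''
      min_len: 8
      max_len: 8
      onlist:
        filename: round3.txt
        location: local
      regions: []
    - region_id: rna-umi
      region_type: umi
      name: rna-umi
      sequence_type: random
      sequence: ''
      min_len: 10
      max_len: 10
      onlist: ~
      regions: []
- region_id: atac
  region_type: atac
  name: atac
  sequence_type: joined
  sequence: XXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXNNNNNNNNAAGCGCNNNNNNNNTGTATTNNNNNNNN
  min_len: 86
  max_len: 86
  onlist: ~
  regions:
  - region_id: atac-read1
    region_type: fastq
    name: atac-read1
    sequence_type: joined
    sequence: XXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXXX
    min_len: 50
    max_len: 50
    onlist: ~
    regions:
    - region_id: atac-gdna
      region_type: gdna
      name: atac-gdna
      sequence_type: random
      sequence: ''
      min_len: 50
      max_len: 50
      onlist: ~
      regions: []
  - region_id: atac-read2
    region_type: fastq
    name: atac-read2
    sequence_type: joined
    sequence: NNNNNNNNAAGCGCNNNNNNNNTGTATTNNNNNNNN
    min_len: 36
    max_len: 36
    onlist: ~
    regions:
    - region_id: atac-bc1
      region_type: barcode
      name: atac-bc1
      sequence_type: onlist
      sequence: ''
      min_len: 8
      max_len: 8
      onlist:
        filename: round1.txt
        location: local
      regions: []
    - region_id: atac-linker1
      region_type: linker
      name: atac-linker1
      sequence_type: fixed
      sequence: AAGCGC
      min_len: 6
      max_len: 6
      onlist: ~
      regions: []
    - region_id: atac-bc2
      region_type: barcode
      name: atac-bc2
      sequence_type: onlist
      sequence: ''
      min_len: 8
      max_len: 8
      onlist:
        filename: round2.txt
        location: local
      regions: []
    - region_id: atac-linker2
      region_type: linker
      name: atac-linker2
      sequence_type: fixed
      sequence: TGTATT
      min_len: 6
      max_len: 6
      onlist: ~
      regions: []
    - region_id: atac-bc3
      region_type: barcode
      name: atac-bc3
      sequence_type: onlist
      sequence: ''
      min_len: 8
      max_len: 8
      onlist:
        filename: round3.txt
        location: local
      regions: []
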