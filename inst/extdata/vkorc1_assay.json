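{
  "label": "VKORC1 G-1639A (rs9923231)",
  "locus": {
    "template": "ACGTACGTACCACAGACGCCAGAGGAAGAGAGACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGAAGACCTGAAAAACAACCATTGGCCAGGTGCGGTGGCTCACGCGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTCCAAACTACTTGGGAGGCTGAGGTACGTACGT",
    "snp_pos": 113,
    "allele_x": "A",
    "allele_y": "G",
    "label": "VKORC1 G-1639A (rs9923231) SYNTHETIC template"
  },
  "primers": {
    "F1": {
      "seq": "CACAGACGCCAGAGGAAGAGAG",
      "start": 11
    },
    "R1": {
      "seq": "CGTGAGCCACCGCACCT",
      "start": 113
    },
    "F2": {
      "seq": "GAAGACCTGAAAAACAACCATTGGCCG",
      "start": 87
    },
    "R2": {
      "seq": "CTCAGCCTCCCAAGTAGTTTGG",
      "start": 273
    }
  },
  "conditions": {
    "na": 0.05,
    "ct": 5e-08,
    "calibration_offset": 0
  },
  "genotype_labels": {
    "XX": "AA",
    "XY": "GA",
    "YY": "GG"
  },
  "published_tm": {
    "F1": 64,
    "R1": 65.1,
    "F2": 64.4,
    "R2": 62.1
  },
  "notes": "X = A (-1639A, low-expression allele), Y = G. SYNTHETIC template reconstructed from primers and product sizes; not genomic reference."
}
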