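{
  "label": "CYP2C9 A1075C / *3 (rs1057910)",
  "locus": {
    "template": "ACGTACGTACCCAGGAAGAGATTGAACGTGTGATTGACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTAGCACGAGGTCCAGAGATACATTGACCTTCTCCCCACCATACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACCGGGTGAGAGAAGTGCATAACTCCGTACGTACG",
    "snp_pos": 117,
    "allele_x": "A",
    "allele_y": "C",
    "label": "CYP2C9 A1075C / *3 (rs1057910) SYNTHETIC template"
  },
  "primers": {
    "F1": {
      "seq": "CCAGGAAGAGATTGAACGTGTGATTG",
      "start": 11
    },
    "R1": {
      "seq": "TGGTGGGGAGAAGGTCAAT",
      "start": 117
    },
    "F2": {
      "seq": "GCACGAGGTCCAGAGATACC",
      "start": 98
    },
    "R2": {
      "seq": "GAGTTATGCACTTCTCTCACCCG",
      "start": 275
    }
  },
  "conditions": {
    "na": 0.05,
    "ct": 5e-08,
    "calibration_offset": 0
  },
  "genotype_labels": {
    "XX": "*1*1",
    "XY": "*1*3",
    "YY": "*3*3"
  },
  "published_tm": {
    "F1": 61.6,
    "R1": 61.3,
    "F2": 61.7,
    "R2": 61.1
  },
  "notes": "X = A (*1 wild type), Y = C (*3, Ile359Leu). SYNTHETIC template reconstructed from primers and product sizes; not genomic reference."
}
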