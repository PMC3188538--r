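{
  "haploid_yeast_reporter": {
    "mode": "drake",
    "T": 1773,
    "C": 4.87,
    "C2": 4.53,
    "adjust": 1,
    "note": "CAN1-style haploid yeast resistance reporter; spectrum-derived correction"
  },
  "diploid_yeast_ura3": {
    "mode": "drake",
    "T": 804,
    "C": 8.18,
    "C2": 6.79,
    "adjust": 1.8,
    "note": "diploid yeast URA3 reporter; external-spectrum constants, 1.8x cross-locus adjustment onto the CAN1 scale"
  },
  "mouse_ouabain": {
    "mode": "target_size",
    "tau": 20,
    "bp_per_allele": 5,
    "n_alleles": 4,
    "note": "mouse ouabain-resistance target: 5 mutable bp per allele x 4 alleles in tetraploid fibroblasts"
  }
}
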