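{
  "snapshot_date": "2018-06-01",
  "databases": ["DGIdb", "MyCancerGenome", "CIViC", "OncoKB", "COSMIC", "ClinVar", "dbSNP"]
}
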