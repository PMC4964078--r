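{
  "coefficients": {
    "Basal": 0.05,
    "Her2": 0.12,
    "LumA": -0.34,
    "LumB": 0.23
  },
  "excluded_genes": ["ANLN", "CDCA1", "CXXC5", "FOXC1", "TMEM45B", "UBE2T"],
  "version": "ROR-S subtype-correlation coefficients; centroid matrix entries are synthetic stand-ins (see pam50_centroids_synthetic.tsv)"
}
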