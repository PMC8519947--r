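{
  "_comment": "Reconstructed gene lists for common immune expression signatures, assembled from the literature for the comparison engine. These are user-editable defaults, not authoritative copies of the original publications; verify against the source papers and your gene annotation before drawing comparative conclusions.",
  "IFNg": {
    "type": "mean",
    "genes": ["IFNG", "STAT1", "IDO1", "CXCL10", "CXCL9", "HLA-DRA"]
  },
  "GEP": {
    "type": "mean",
    "genes": ["CCL5", "CD27", "CD274", "CD276", "CD8A", "CMKLR1", "CXCL9",
              "CXCR6", "HLA-DQA1", "HLA-DRB1", "HLA-E", "IDO1", "LAG3",
              "NKG7", "PDCD1LG2", "PSMB10", "STAT1", "TIGIT"]
  },
  "Chemokine": {
    "type": "mean",
    "genes": ["CCL2", "CCL3", "CCL4", "CCL5", "CCL8", "CCL18", "CCL19",
              "CCL21", "CXCL9", "CXCL10", "CXCL11", "CXCL13"]
  },
  "Immunoscore": {
    "type": "mean",
    "genes": ["CD3D", "CD3E", "CD3G", "CD8A", "CD8B", "GZMB", "PRF1"]
  },
  "CYT": {
    "type": "geomean",
    "genes": ["GZMA", "PRF1"]
  },
  "MHC.I": {
    "type": "mean",
    "genes": ["HLA-A", "HLA-B", "HLA-C", "B2M", "TAP1", "TAP2"]
  },
  "MHC.II": {
    "type": "mean",
    "genes": ["HLA-DRA", "HLA-DRB1", "HLA-DQA1", "HLA-DQB1", "HLA-DPA1",
              "HLA-DPB1"]
  },
  "CD8A.CSF1R": {
    "type": "ratio",
    "num": "CD8A",
    "den": "CSF1R"
  },
  "CheckpointPairs": {
    "type": "pairs",
    "_comment": "Illustrative immune-checkpoint gene-pair score in the IMPRES style; replace with the published pair list for faithful comparison.",
    "pairs": [["PDCD1", "CD274"], ["CTLA4", "CD86"], ["CD27", "CD40"],
              ["LAG3", "HLA-DRA"], ["HAVCR2", "CEACAM1"], ["TIGIT", "PVR"],
              ["BTLA", "TNFRSF14"], ["CD28", "CD80"], ["ICOS", "ICOSLG"],
              ["TNFRSF9", "TNFSF9"], ["CD40LG", "CD40"], ["CD276", "CD8A"],
              ["VSIR", "CD4"], ["CD200R1", "CD200"], ["TNFRSF4", "TNFSF4"]]
  }
}
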