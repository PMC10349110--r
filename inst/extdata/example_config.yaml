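# Synthetic-mode pipeline configuration: generates the default 188-observer,
# 20-item proficiency study and runs every analysis stage on it.
synthetic:
  preset: enfsi
  seed: 1
out_dir: facefuse_out
stages: [validate, accuracy, sdt, similarity, fusion]
sdt:
  inconclusive: exclude     # 0 responses are non-decisions (alternative: different)
similarity:
  heatmaps: true
fusion:
  seed: 1
  n_samples: 1000
  compositions:
    - forensic_examiner: 1
    - forensic_examiner: 2
    - super_recognizer: 2
    - forensic_examiner: 1
      dnn: 1
    - super_recognizer: 1
      dnn: 1
    - forensic_examiner: 1
      super_recognizer: 1
      dnn: 1
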