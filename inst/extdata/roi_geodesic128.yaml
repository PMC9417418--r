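# Approximate ROI membership for a 128-channel HydroCel geodesic sensor
# net (10-10 equivalents in comments). User-replaceable: any YAML mapping
# ROI names to electrode-label lists can be loaded with read_roi_layout().
occipital:
  - E70   # O1
  - E75   # Oz
  - E83   # O2
  - E62   # POz
  - E71
  - E76
  - E66   # PO3
  - E84   # PO4
prefrontal:
  - E22   # Fp1
  - E15   # Fpz
  - E9    # Fp2
  - E16   # AFz
  - E18   # AF3
  - E10   # AF4
sensorimotor:
  - E36   # C3
  - E104  # C4
  - E55   # CPz (vertex reference neighbourhood)
  - E30   # C1
  - E105
  - E87
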