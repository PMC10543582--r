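# Published worked-example constants from a three-scanner AD/CN ALPS study
# (group sizes and AD-vs-CN Cohen's d before/after harmonization).
n_ad: 45
n_cn: 82
alpha: 0.05
cohens_d:
  alps_left:
    before: 0.288
    after: 0.438
  alps_right:
    before: 0.328
    after: 0.480
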