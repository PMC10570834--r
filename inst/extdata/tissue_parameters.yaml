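# Radiobiological model constants for whole-breast plan evaluation.
# alpha_beta in Gy; a, gamma, m, n dimensionless; d50 in Gy.
# 'lung' applies to both the ipsilateral and contralateral lung.
ptv:
  alpha_beta: 4
  a: -7.2
  gamma: 1.3
  d50: 30.89
heart:
  alpha_beta: 4
  d50: 48
  m: 0.1
  "n": 0.35
lung:
  alpha_beta: 4
  d50: 37.6
  m: 0.35
  "n": 0.87
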