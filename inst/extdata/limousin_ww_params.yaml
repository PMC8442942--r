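countries:
- CZE
- DFS
- ESP
- GBR
- IRL
- FRA
- DEU
- CHE
genetic_variances:
  direct:
    CZE: 310.0
    DFS: 269.0
    ESP: 136.0
    GBR: 268.0
    IRL: 450.0
    FRA: 242.0
    DEU: 383.0
    CHE: 130.0
  maternal:
    CZE: 197.0
    DFS: 120.0
    ESP: 68.0
    GBR: 55.0
    IRL: 194.0
    FRA: 62.0
    DEU: 326.0
    CHE: 54.0
correlations:
- - 1.0
  - 0.87
  - 0.74
  - 0.71
  - 0.83
  - 0.76
  - 0.76
  - 0.85
  - -0.12
  - -0.05
  - 0.03
  - 0.14
  - -0.03
  - -0.02
  - -0.02
  - 0.12
- - 0.87
  - 1.0
  - 0.77
  - 0.82
  - 0.76
  - 0.89
  - 0.94
  - 0.81
  - 0.04
  - -0.14
  - 0.09
  - 0.06
  - 0.07
  - -0.05
  - -0.09
  - 0.11
- - 0.74
  - 0.77
  - 1.0
  - 0.94
  - 0.87
  - 0.77
  - 0.76
  - 0.76
  - 0.07
  - 0.02
  - -0.22
  - -0.03
  - -0.06
  - -0.03
  - -0.03
  - 0.07
- - 0.71
  - 0.82
  - 0.94
  - 1.0
  - 0.91
  - 0.82
  - 0.77
  - 0.71
  - 0.12
  - -0.01
  - -0.08
  - -0.1
  - -0.05
  - -0.06
  - -0.01
  - 0.08
- - 0.83
  - 0.76
  - 0.87
  - 0.91
  - 1.0
  - 0.76
  - 0.62
  - 0.7
  - -0.01
  - -0.02
  - -0.09
  - -0.03
  - -0.19
  - -0.09
  - 0.06
  - 0.03
- - 0.76
  - 0.89
  - 0.77
  - 0.82
  - 0.76
  - 1.0
  - 0.81
  - 0.7
  - -0.1
  - -0.11
  - -0.05
  - -0.14
  - -0.12
  - -0.33
  - -0.1
  - -0.05
- - 0.76
  - 0.94
  - 0.76
  - 0.77
  - 0.62
  - 0.81
  - 1.0
  - 0.7
  - 0.08
  - -0.07
  - 0.05
  - 0.07
  - 0.12
  - -0.01
  - -0.24
  - 0.06
- - 0.85
  - 0.81
  - 0.76
  - 0.71
  - 0.7
  - 0.7
  - 0.7
  - 1.0
  - 0.01
  - -0.01
  - 0.02
  - 0.08
  - 0.11
  - 0.08
  - 0.09
  - 0.4
- - -0.12
  - 0.04
  - 0.07
  - 0.12
  - -0.01
  - -0.1
  - 0.08
  - 0.01
  - 1.0
  - 0.68
  - 0.67
  - 0.79
  - 0.69
  - 0.85
  - 0.68
  - 0.73
- - -0.05
  - -0.14
  - 0.02
  - -0.01
  - -0.02
  - -0.11
  - -0.07
  - -0.01
  - 0.68
  - 1.0
  - 0.68
  - 0.69
  - 0.68
  - 0.69
  - 0.68
  - 0.68
- - 0.03
  - 0.09
  - -0.22
  - -0.08
  - -0.09
  - -0.05
  - 0.05
  - 0.02
  - 0.67
  - 0.68
  - 1.0
  - 0.7
  - 0.81
  - 0.71
  - 0.67
  - 0.67
- - 0.14
  - 0.06
  - -0.03
  - -0.1
  - -0.03
  - -0.14
  - 0.07
  - 0.08
  - 0.79
  - 0.69
  - 0.7
  - 1.0
  - 0.72
  - 0.87
  - 0.69
  - 0.66
- - -0.03
  - 0.07
  - -0.06
  - -0.05
  - -0.19
  - -0.12
  - 0.12
  - 0.11
  - 0.69
  - 0.68
  - 0.81
  - 0.72
  - 1.0
  - 0.82
  - 0.68
  - 0.65
- - -0.02
  - -0.05
  - -0.03
  - -0.06
  - -0.09
  - -0.33
  - -0.01
  - 0.08
  - 0.85
  - 0.69
  - 0.71
  - 0.87
  - 0.82
  - 1.0
  - 0.69
  - 0.77
- - -0.02
  - -0.09
  - -0.03
  - -0.01
  - 0.06
  - -0.1
  - -0.24
  - 0.09
  - 0.68
  - 0.68
  - 0.67
  - 0.69
  - 0.68
  - 0.69
  - 1.0
  - 0.66
- - 0.12
  - 0.11
  - 0.07
  - 0.08
  - 0.03
  - -0.05
  - 0.06
  - 0.4
  - 0.73
  - 0.68
  - 0.67
  - 0.66
  - 0.65
  - 0.77
  - 0.66
  - 1.0
residual_variances:
  CZE: 671.0
  DFS: 633.2
  ESP: 312.8
  GBR: 695.4
  IRL: 1066.0
  FRA: 615.6
  DEU: 823.0
  CHE: 310.0
pe_variances:
  CZE: 62.0
  DFS: 53.8
  ESP: 27.2
  GBR: 53.6
  IRL: 90.0
  FRA: 48.4
  DEU: 0.0
  CHE: 26.0
random_env_variances:
  CZE: ~
  DFS: ~
  ESP: ~
  GBR: ~
  IRL: ~
  FRA: ~
  DEU: ~
  CHE: ~
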