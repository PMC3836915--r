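# Worked simulation config: 50 patients spread over the latent
# continuum, each judging the radius-1 pivot neighborhood of their own
# state.  gamma holds the generating attribute-level decrements in
# design-vector order (MO2 MO3 SC2 SC3 UA2 UA3 PD2 PD3 AD2 AD3).
system_file: eq5d3l.yaml
n_respondents: 50
seed: 20260927
theta:
  family: normal
  mean: -1.0
  sd: 1.2
gamma:
  - -0.30
  - -0.90
  - -0.25
  - -0.80
  - -0.20
  - -0.70
  - -0.40
  - -1.10
  - -0.35
  - -1.00
design:
  type: pivot
  radius: 1
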