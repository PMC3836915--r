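# EQ-5D-like descriptive system: 5 attributes, 3 ordered levels each
# (level 1 = best).  Synthetic stand-in used in examples and simulations.
attributes:
  MO:  # mobility
    - no problems walking about
    - some problems walking about
    - confined to bed
  SC:  # self-care
    - no problems with self-care
    - some problems washing or dressing
    - unable to wash or dress
  UA:  # usual activities
    - no problems with usual activities
    - some problems performing usual activities
    - unable to perform usual activities
  PD:  # pain / discomfort
    - no pain or discomfort
    - moderate pain or discomfort
    - extreme pain or discomfort
  AD:  # anxiety / depression
    - not anxious or depressed
    - moderately anxious or depressed
    - extremely anxious or depressed
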