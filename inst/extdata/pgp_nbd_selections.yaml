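# Example domain selections for murine P-glycoprotein (single-chain ABC
# transporter): approximate NBD1/NBD2 residue ranges, for demonstration of
# the selection format only. Residue ranges for center-of-mass separation
# measurements are always user configuration.
NBD1:
  - chain: A
    start: 395
    end: 627
NBD2:
  - chain: A
    start: 1043
    end: 1271
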