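# Patient-style personalization of the driving pressures plus a relaxation
# factor suited to millilitre-scale perfusion territories.
peak_pressure_mmHg: 140
period: 0.714
systolic_fraction: 0.37
relaxation: 0.04
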