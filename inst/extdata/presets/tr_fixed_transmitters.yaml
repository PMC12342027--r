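# Transmitters fixed onto the electrode surface, receivers stirred
preset: tr_fixed_transmitters
charge_duration: 30
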