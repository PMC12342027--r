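# Fully static (biofilm-like) Transmitter/Receiver network, electrode induction
preset: tr_fully_static
charge_duration: 30
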