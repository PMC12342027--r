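# Transmitter/Receiver co-culture, electrode induction, stirred culture
preset: tr_electrical
charge_duration: 30
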