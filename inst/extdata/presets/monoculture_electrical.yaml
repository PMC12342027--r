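# Monoculture, electrode-generated hydrogen peroxide, stirred culture
preset: monoculture_electrical
charge_duration: 30
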