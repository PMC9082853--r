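name	length_bp
chrA	1000000
chrB	2000000
chrC	1500000
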