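chrA	1000000	52	60	61
chrB	2000000	1016720	60	61
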