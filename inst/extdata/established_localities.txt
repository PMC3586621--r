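# Localities constituting the established invaded range
# (northern North Island of New Zealand)
Auckland
Hamilton
Whangarei
Tauranga
Waihi Beach
Thames
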