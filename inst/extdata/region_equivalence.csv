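locality_a,locality_b,tier
Caboolture,Brisbane (North),exact
Gold Coast,Gold Coast-Lamington NP,exact
Brisbane (Samford),Brisbane (North),exact
Bega NSW,NSW/VIC border region,exact
Eden NSW,NSW/VIC border region,exact
Melbourne,Melbourne region,exact
Brisbane,Gold Coast-Lamington NP,near
North Sydney,North NSW coast-Wyong,near
Sydney,North NSW coast-Wyong,near
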