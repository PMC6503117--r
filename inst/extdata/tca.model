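# Simplified TCA cycle with atom transitions.
# Substrates: AcCoA, Asp. Products: Glu, CO2.
# Fumarate and succinate are rotationally symmetric (1-4 / 2-3 axis).
v1: OAA (abcd) + AcCoA (ef) -> Cit (dcbfea)
v2: Cit (abcdef) -> AKG (abcde) + CO2 (f)
v3: AKG (abcde) -> Glu (abcde)
v4: AKG (abcde) -> Suc (bcde) + CO2 (a)
v5: Suc (abcd) -> Fum (abcd)
v6: Fum (abcd) <-> OAA (abcd)
v7: Asp (abcd) -> OAA (abcd)
symmetric: Fum 1-4,2-3
symmetric: Suc 1-4,2-3
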