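# Xylose catabolism of Clostridium acetobutylicum.
# SYNTHETIC transcription: reconstructed from the published network
# diagram and standard clostridial biochemistry (phosphoketolase split,
# reversible non-oxidative pentose phosphate pathway, EMP glycolysis,
# acetate from acetyl-phosphate, AcCoA-derived fermentation products).
# Oxidative PPP and the TCA cycle are deliberately absent. Uptake: v1;
# phosphoketolase: v2 (flux ratio of interest is v2/v1).
v1: Xyl (abcde) -> X5P (abcde)
v2: X5P (abcde) -> AcP (ab) + GAP (cde)
v3: X5P (abcde) <-> Ru5P (abcde)
v4: Ru5P (abcde) <-> R5P (abcde)
v5: X5P (abcde) + R5P (fghij) <-> S7P (abfghij) + GAP (cde)
v6: S7P (abcdefg) + GAP (hij) <-> E4P (defg) + F6P (abchij)
v7: X5P (abcde) + E4P (fghi) <-> F6P (abfghi) + GAP (cde)
v8: F6P (abcdef) -> FBP (abcdef)
v9: FBP (abcdef) <-> DHAP (abc) + GAP (def)
v10: DHAP (abc) <-> GAP (cba)
v11: GAP (abc) <-> G3P (abc)
v12: G3P (abc) <-> PEP (abc)
v13: PEP (abc) -> Pyr (abc)
v14: Pyr (abc) -> AcCoA (bc) + CO2 (a)
v15: AcP (ab) <-> AcCoA (ab)
v16: AcP (ab) -> AC (ab)
v17: AcCoA (ab) -> EtOH (ab)
v18: AcCoA (ab) + AcCoA (cd) -> AcAcCoA (abcd)
v19: AcAcCoA (abcd) -> BU (abcd)
v20: AcAcCoA (abcd) -> BuOH (abcd)
v21: AcAcCoA (abcd) -> ACE (bcd) + CO2 (a)
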