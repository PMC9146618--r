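canonical_name,synonyms,ei_score,provenance
water,,10,GSK solvent selection guide environmental-impact score (reference validation value)
ethanol,ethyl alcohol; EtOH,8,GSK solvent selection guide environmental-impact score (reference validation value)
propanol,1-propanol; 2-propanol; isopropanol; n-propanol; IPA,7,GSK guide score as used in the SSE reference method; the source does not state the propanol isomer so both map here
methylene chloride,dichloromethane; DCM,6,GSK solvent selection guide environmental-impact score (reference validation value)
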