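patient_id,birth_year,sex,region
A01,1955,F,south
A02,1972,M,northeast
A03,1988,F,missing
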