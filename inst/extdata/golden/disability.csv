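patient_id,start_date,end_date,paid_usd
A03,2011-03-07,2011-03-18,1200.00
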