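patient_id,service_date,setting,dx1,dx2,dx3,dx4,paid_usd
A01,2010-01-15,outpatient,696.1,"","","",0.00
A01,2010-09-02,outpatient,696.1,"","","",0.00
A01,2011-04-10,outpatient,"","","","",152.37
A01,2011-04-11,pharmacy,"","","","",48.03
A02,2010-03-03,outpatient,696.8,"","","",0.00
A02,2011-06-20,outpatient,696.8,"","","",0.00
A02,2011-08-01,inpatient,"","","","",5200.00
A02,2011-08-02,inpatient,"","","","",4100.50
A02,2011-08-03,inpatient,"","","","",3999.50
A03,2010-05-05,outpatient,696.1,"","","",0.00
A03,2010-11-11,outpatient,696.1,"","","",0.00
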