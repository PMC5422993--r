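patient_id,year_month,medical,pharmacy,plan_type,hpm_std_eligible
A01,2010-01,1,1,PPO,0
A01,2010-02,1,1,PPO,0
A01,2010-03,1,1,PPO,0
A01,2010-04,1,1,PPO,0
A01,2010-05,1,1,PPO,0
A01,2010-06,1,1,PPO,0
A01,2010-07,1,1,PPO,0
A01,2010-08,1,1,PPO,0
A01,2010-09,1,1,PPO,0
A01,2010-10,1,1,PPO,0
A01,2010-11,1,1,PPO,0
A01,2010-12,1,1,PPO,0
A01,2011-01,1,1,PPO,0
A01,2011-02,1,1,PPO,0
A01,2011-03,1,1,PPO,0
A01,2011-04,1,1,PPO,0
A01,2011-05,1,1,PPO,0
A01,2011-06,1,1,PPO,0
A01,2011-07,1,1,PPO,0
A01,2011-08,1,1,PPO,0
A01,2011-09,1,1,PPO,0
A01,2011-10,1,1,PPO,0
A01,2011-11,1,1,PPO,0
A01,2011-12,1,1,PPO,0
A02,2010-01,1,1,PPO,0
A02,2010-02,1,1,PPO,0
A02,2010-03,1,1,PPO,0
A02,2010-04,1,1,PPO,0
A02,2010-05,1,1,PPO,0
A02,2010-06,1,1,PPO,0
A02,2010-07,1,1,PPO,0
A02,2010-08,1,1,PPO,0
A02,2010-09,1,1,PPO,0
A02,2010-10,1,1,PPO,0
A02,2010-11,1,1,PPO,0
A02,2010-12,1,1,PPO,0
A02,2011-01,1,1,PPO,0
A02,2011-02,1,1,PPO,0
A02,2011-03,1,1,PPO,0
A02,2011-04,1,1,PPO,0
A02,2011-05,1,1,PPO,0
A02,2011-06,1,1,PPO,0
A02,2011-07,1,1,PPO,0
A02,2011-08,1,1,PPO,0
A02,2011-09,1,1,PPO,0
A02,2011-10,1,1,PPO,0
A02,2011-11,1,1,PPO,0
A02,2011-12,1,1,PPO,0
A03,2010-01,1,1,PPO,0
A03,2010-02,1,1,PPO,0
A03,2010-03,1,1,PPO,0
A03,2010-04,1,1,PPO,0
A03,2010-05,1,1,PPO,0
A03,2010-06,1,1,PPO,0
A03,2010-07,1,1,PPO,0
A03,2010-08,1,1,PPO,0
A03,2010-09,1,1,PPO,0
A03,2010-10,1,1,PPO,0
A03,2010-11,1,1,PPO,0
A03,2010-12,1,1,PPO,0
A03,2011-01,1,1,PPO,1
A03,2011-02,1,1,PPO,1
A03,2011-03,1,1,PPO,1
A03,2011-04,1,1,PPO,1
A03,2011-05,1,1,PPO,1
A03,2011-06,1,1,PPO,1
A03,2011-07,1,1,PPO,1
A03,2011-08,1,1,PPO,1
A03,2011-09,1,1,PPO,1
A03,2011-10,1,1,PPO,1
A03,2011-11,1,1,PPO,1
A03,2011-12,1,1,PPO,1
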