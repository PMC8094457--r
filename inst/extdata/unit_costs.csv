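item,unit,unit_cost,price_year
theatre_minute,per minute,16.00,2016
surgeon_minute,per minute,2.40,2016
anaesthetist_minute,per minute,2.20,2016
nurse_minute,per minute,0.80,2016
consumable_pack,per item,120.00,2017
bed_day,per day,400.00,2015
catheter_day,per day,2.50,2017
gp_visit,per visit,38.00,2017
outpatient_visit,per visit,125.00,2016
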