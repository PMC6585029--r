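scenario,element,count
ti,syringe_1m,0
ti,syringe_3m,0
ti,gp_visits,2883
ti,psychiatrist_visits,34109
ti,ambulatory_visits,1849
ti,general_bed_days,791
ti,psychiatric_bed_days,43864
pp1m,syringe_1m,805
pp1m,syringe_3m,0
pp1m,gp_visits,3322
pp1m,psychiatrist_visits,35224
pp1m,ambulatory_visits,701
pp1m,general_bed_days,335
pp1m,psychiatric_bed_days,16406
pp3m,syringe_1m,594
pp3m,syringe_3m,2564
pp3m,gp_visits,3447
pp3m,psychiatrist_visits,35528
pp3m,ambulatory_visits,371
pp3m,general_bed_days,178
pp3m,psychiatric_bed_days,8699
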