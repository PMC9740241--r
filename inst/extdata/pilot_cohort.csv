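patient_id,femur_id,physician_risk,bos_risk,treatment,fractured_6mo,died_6mo,delivery_days,bos_used
p01,f01,low,low,none,FALSE,TRUE,0,TRUE
p02,f02,low,low,rt_single,FALSE,FALSE,0,TRUE
p03,f03,low,low,rt_single,FALSE,FALSE,0,TRUE
p04,f04,low,low,rt_single,FALSE,TRUE,0,TRUE
p05,f05,low,low,rt_single,FALSE,FALSE,0,TRUE
p06,f06,low,low,rt_multiple,FALSE,FALSE,0,TRUE
p07,f07,low,moderate,rt_single,FALSE,TRUE,0,TRUE
p07,f08,low,moderate,rt_multiple,FALSE,TRUE,0,TRUE
p08,f09,low,moderate,rt_multiple,FALSE,FALSE,0,TRUE
p09,f10,low,moderate,rt_multiple,FALSE,FALSE,0,TRUE
p10,f11,low,moderate,rt_multiple,FALSE,TRUE,0,TRUE
p11,f12,low,moderate,rt_multiple,FALSE,FALSE,0,FALSE
p12,f13,low,moderate,rt_multiple,FALSE,FALSE,0,FALSE
p13,f14,low,high,rt_single,FALSE,TRUE,0,TRUE
p14,f15,low,high,rt_single,FALSE,FALSE,1,TRUE
p15,f16,low,high,rt_single,FALSE,FALSE,1,TRUE
p16,f17,low,high,rt_multiple,TRUE,TRUE,1,TRUE
p17,f18,low,high,rt_multiple,FALSE,FALSE,1,TRUE
p18,f19,low,high,rt_multiple,FALSE,FALSE,1,TRUE
p19,f20,low,high,rt_multiple,FALSE,TRUE,1,TRUE
p19,f21,low,high,rt_multiple,FALSE,TRUE,1,TRUE
p20,f22,low,high,rt_multiple,FALSE,FALSE,1,TRUE
p21,f23,low,high,rt_multiple,FALSE,FALSE,1,TRUE
p22,f24,low,high,rt_multiple,FALSE,TRUE,1,TRUE
p23,f25,low,high,rt_multiple,FALSE,FALSE,1,TRUE
p24,f26,low,high,rt_multiple,FALSE,FALSE,1,TRUE
p25,f27,low,high,rt_multiple,FALSE,TRUE,1,TRUE
p26,f28,low,high,elective_surgery,FALSE,FALSE,1,TRUE
p27,f29,high,low,rt_single,FALSE,FALSE,1,TRUE
p28,f30,high,low,rt_single,FALSE,TRUE,1,TRUE
p28,f31,high,low,rt_multiple,FALSE,TRUE,1,TRUE
p29,f32,high,low,rt_multiple,FALSE,FALSE,1,TRUE
p30,f33,high,low,rt_multiple,FALSE,FALSE,1,TRUE
p31,f34,high,low,rt_multiple,FALSE,TRUE,1,TRUE
p32,f35,high,low,rt_multiple,FALSE,FALSE,1,TRUE
p33,f36,high,moderate,none,FALSE,FALSE,1,TRUE
p34,f37,high,moderate,rt_multiple,FALSE,TRUE,1,TRUE
p35,f38,high,high,elective_surgery,TRUE,FALSE,2,TRUE
p36,f39,high,high,elective_surgery,TRUE,FALSE,2,TRUE
p37,f40,high,high,elective_surgery,FALSE,TRUE,2,TRUE
p38,f41,high,high,elective_surgery,FALSE,FALSE,2,TRUE
p39,f42,high,high,elective_surgery,FALSE,FALSE,2,TRUE
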