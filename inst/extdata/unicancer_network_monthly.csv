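center_id,year,month,patient_status,tumor_group,sex,stage,count
NETWORK,2019,1,new,all,all,all,7069
NETWORK,2019,2,new,all,all,all,6384
NETWORK,2019,3,new,all,all,all,6736
NETWORK,2019,4,new,all,all,all,6673
NETWORK,2019,5,new,all,all,all,6672
NETWORK,2019,6,new,all,all,all,6319
NETWORK,2019,7,new,all,all,all,7306
NETWORK,2020,1,new,all,all,all,7378
NETWORK,2020,2,new,all,all,all,6725
NETWORK,2020,3,new,all,all,all,6645
NETWORK,2020,4,new,all,all,all,5296
NETWORK,2020,5,new,all,all,all,5218
NETWORK,2020,6,new,all,all,all,6208
NETWORK,2020,7,new,all,all,all,6477
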