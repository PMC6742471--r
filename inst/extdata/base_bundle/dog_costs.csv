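component,band,companion,certified,alfa,beta
purchase,year1,1151,1151,308,32
annual_upkeep,year1,1332,1332,92,10
suitability_tests,year1,0,193,NA,NA
annual_upkeep,year2,1332,1332,92,10
training,year2,0,7746,NA,NA
capes,year2,0,211,NA,NA
annual_upkeep,subsequent,1332,1332,92,10
maintenance_test,subsequent,0,88,NA,NA
health_declaration,subsequent,0,59,NA,NA
printed_total,year1,2482,2676,NA,NA
printed_total,year2,1332,9288,NA,NA
printed_total,subsequent,1332,1478,NA,NA
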