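category_code,scenario_class,is_aerosol,product_amount_g,weight_fraction,room_volume_m3,dilution_fraction,event_duration_h,events_per_day,skin_contact_area_cm2,thickness_layer_cm,contact_density_g_cm3,transfer_factor,ingested_amount_g,mouthed_area_cm2,population,provenance
PC9a-spray-paint,product,TRUE,300,0.5,20,1,2,1,0,0.01,1,1,0,10,adult,fixture-nonauthoritative
PC9a-wall-paint,product,FALSE,3750,0.25,20,1,2,1,428,0.01,1,1,0,10,adult,fixture-nonauthoritative
PC35-all-purpose-cleaner,product,FALSE,150,0.1,20,1,0.5,1,428,0.01,1,1,0,10,adult,fixture-nonauthoritative
PC3-air-care-instant,product,TRUE,10,0.2,20,1,0.25,1,0,0.01,1,1,0,10,adult,fixture-nonauthoritative
AC13-flooring,article,FALSE,1000,0.1,20,1,8,1,8750,0.01,1,1,0,10,adult,printed-in-paper
AC13-toys-plastic,article,FALSE,50,0.1,20,1,1,1,100,0.001,1,1,0.043,10,child,fixture-nonauthoritative
AC13-teething-ring,article,FALSE,20,0.2,20,1,1,1,10,0.001,1,1,0.215,10,child,fixture-nonauthoritative
AC5-toys-cuddly,article,FALSE,300,0.05,20,1,1,1,500,0.01,1,1,0.2,10,child,fixture-nonauthoritative
AC5-bedding-mattress,article,FALSE,2000,0.1,20,1,8,1,17500,0.001,1,1,0.01,10,child,fixture-nonauthoritative
AC8-printed-paper,article,FALSE,100,0.3,20,1,1,1,200,0.001,1,1,0.1,10,child,fixture-nonauthoritative
AC5-clothing,article,FALSE,500,0.05,20,1,8,1,17500,0.001,1,1,0,10,adult,fixture-nonauthoritative
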