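name,value,units
blood_air_partition,9.7,unitless
partition_fat,12.4,unitless
partition_liver,1.46,unitless
partition_kidney,1.0,unitless
partition_richly,1.46,unitless
partition_slowly,0.82,unitless
partition_skin,1.0,unitless
partition_lung,1.46,unitless
partition_stomach,1.0,unitless
partition_intestine,1.0,unitless
vmax_c_liver1,4.0,mg/h/kg^0.75
vmax_c_liver2,0,mg/h/kg^0.75
vmax_c_lung,0.41,mg/h/kg^0.75
vmax_c_kidney,0,mg/h/kg^0.75
km_liver1,0.4,mg/L
km_liver2,1.0,mg/L
km_lung,0.4,mg/L
km_kidney,1.0,mg/L
kf_liver,2.0,/h
kf_lung,0.2,/h
kf_kidney,0,/h
kf_stomach,0,/h
kf_intestine,0,/h
oral_absorption_rate_stomach,5.0,/h
oral_absorption_rate_intestine,0,/h
stomach_to_intestine_rate,0,/h
fecal_transit_rate,0,/h
dermal_permeability,0,cm/h
urinary_clearance_c,0,L/h/kg^0.75
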