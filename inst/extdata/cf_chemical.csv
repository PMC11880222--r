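name,value,units
blood_air_partition,7.43,unitless
partition_fat,38.0,unitless
partition_liver,2.3,unitless
partition_kidney,1.5,unitless
partition_richly,2.3,unitless
partition_slowly,1.6,unitless
partition_skin,1.0,unitless
partition_lung,1.0,unitless
partition_stomach,1.0,unitless
partition_intestine,1.0,unitless
vmax_c_liver1,7.0,mg/h/kg^0.75
vmax_c_liver2,0,mg/h/kg^0.75
vmax_c_lung,0,mg/h/kg^0.75
vmax_c_kidney,0.6,mg/h/kg^0.75
km_liver1,0.45,mg/L
km_liver2,1.0,mg/L
km_lung,1.0,mg/L
km_kidney,0.35,mg/L
kf_liver,0,/h
kf_lung,0,/h
kf_kidney,0,/h
kf_stomach,0,/h
kf_intestine,0,/h
oral_absorption_rate_stomach,3.0,/h
oral_absorption_rate_intestine,1.0,/h
stomach_to_intestine_rate,1.5,/h
fecal_transit_rate,0.1,/h
dermal_permeability,0,cm/h
urinary_clearance_c,0,L/h/kg^0.75
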