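name,value,units
body_weight,70,kg
volume_fraction_arterial,0.0204,L/kg
volume_fraction_venous,0.0454,L/kg
volume_fraction_lung,0.0076,L/kg
volume_fraction_fat,0.19,L/kg
volume_fraction_liver,0.026,L/kg
volume_fraction_kidney,0.0044,L/kg
volume_fraction_richly,0.05,L/kg
volume_fraction_slowly,0.48,L/kg
volume_fraction_skin,0.037,L/kg
volume_fraction_stomach,0.0021,L/kg
volume_fraction_intestine,0.0171,L/kg
flow_fraction_fat,0.05,fraction
flow_fraction_liver,0.07,fraction
flow_fraction_kidney,0.175,fraction
flow_fraction_richly,0.19,fraction
flow_fraction_slowly,0.17,fraction
flow_fraction_skin,0.058,fraction
flow_fraction_stomach,0.024,fraction
flow_fraction_intestine,0.238,fraction
flow_fraction_lung,0.025,fraction
cardiac_output_c,16.5,L/h/kg^0.75
alveolar_ventilation_c,20.2,L/h/kg^0.75
skin_area_c,1059,cm^2/kg^0.667
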