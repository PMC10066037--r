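environment_group	salinity	zone	water_depth_class	vent_influence	artificial	sample_type
hydrothermal_plume	marine	pelagic	deep-sea	TRUE	FALSE	water
hydrothermal_vent_substrate	marine	benthic	deep-sea	TRUE	FALSE	substrate-associated
marine_water_column	marine	pelagic	deep-sea	FALSE	FALSE	water
coastal_water	marine	pelagic	coastal	FALSE	FALSE	water
marine_sediment	marine	benthic	deep-sea	FALSE	FALSE	substrate-associated
coastal_sediment	marine	benthic	coastal	FALSE	FALSE	substrate-associated
brackish_water	brackish	pelagic	coastal	FALSE	FALSE	water
brackish_sediment	brackish	benthic	coastal	FALSE	FALSE	substrate-associated
freshwater	fresh	pelagic	coastal	FALSE	FALSE	water
subsurface_aquifer	fresh	subsurface	coastal	FALSE	FALSE	substrate-associated
artificial_system	marine	subsurface	coastal	FALSE	TRUE	substrate-associated
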