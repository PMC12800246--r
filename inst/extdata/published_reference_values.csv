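dataset,quantity,value,unit
body,pc1_prop_variance,49.20,percent
body,pc2_prop_variance,14.94,percent
cheek,pc1_prop_variance,40.25,percent
cheek,pc2_prop_variance,15.48,percent
skull_roof,pc1_prop_variance,52.46,percent
skull_roof,pc2_prop_variance,17.59,percent
cheek,procrustes_variance_Actinistia,0.0961,shape_units_sq
cheek,procrustes_variance_marine,0.1297,shape_units_sq
cheek,procrustes_variance_freshwater,0.0397,shape_units_sq
body,disparity_share_Actinistia,43.89,percent
body,disparity_share_freshwater,49.04,percent
body,disparity_share_bay,33.54,percent
cheek,disparity_share_Actinistia,47.93,percent
cheek,disparity_share_marine,52.73,percent
body,disparity_share_Frasnian,17.55,percent
body,disparity_share_Famennian,20.44,percent
body,disparity_share_Serpukhovian,35.53,percent
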