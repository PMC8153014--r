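class,training_area_ha,training_pixels,test_points
mangrove swamp,24.1,1862,265
mixed swamp,241.3,5727,589
palm swamp,50.9,1312,334
bog plain,136.98,3479,269
natural forest,331.3,11738,115
sparse vegetation,5.8,301,242
coconut,39.6,1350,282
rubber,49.3,1734,228
oil palm,26,656,70
built-up,41.7,1215,258
bare surface,3.5,101,172
water,709,18195,87
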