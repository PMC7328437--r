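group,activity,metric,value,tolerance,tolerance_type
commuter,shop_food,participation,27,3,pp
commuter,shop_food,mean_duration,41,0.15,rel
commuter,shop_food,median_duration,30,0.15,rel
retired,shop_food,participation,49,3,pp
retired,shop_food,mean_duration,69,0.15,rel
retired,shop_food,median_duration,50,0.15,rel
commuter,sports,participation,16.2,3,pp
retired,sports,participation,17.8,3,pp
commuter,lunch_out,participation,4.5,3,pp
commuter,evening_social,participation,7.9,3,pp
retired,lunch_out,participation,7.9,3,pp
retired,evening_social,participation,7.9,3,pp
retired,shop_leisure,participation,16.6,3,pp
commuter,work,mean_duration,480,30,abs_min
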