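criterion,temp_dev,precip_dev,lst_winter,precip_winter,ndvi_dev,land_cover,aspect,slope,clay,sand,dist_river,dist_lake
temp_dev,            1,            1,            2,            3,            1,            2,            6,            4,            4,            4,            3,            4
precip_dev,            1,            1,            1,            2,            1,            1,            4,            3,            3,            3,            2,            3
lst_winter,          0.5,            1,            1,            1,          0.5,            1,            3,            2,            2,            2,            2,            2
precip_winter, 0.3333333333,          0.5,            1,            1,          0.5,          0.5,            2,            1,            1,            2,            1,            2
ndvi_dev,            1,            1,            2,            2,            1,            1,            5,            3,            3,            4,            2,            4
land_cover,          0.5,            1,            1,            2,            1,            1,            4,            2,            2,            3,            2,            3
aspect, 0.1666666667,         0.25, 0.3333333333,          0.5,          0.2,         0.25,            1,          0.5,          0.5,          0.5,          0.5,          0.5
slope,         0.25, 0.3333333333,          0.5,            1, 0.3333333333,          0.5,            2,            1,            1,            1,            1,            1
clay,         0.25, 0.3333333333,          0.5,            1, 0.3333333333,          0.5,            2,            1,            1,            1,            1,            1
sand,         0.25, 0.3333333333,          0.5,          0.5,         0.25, 0.3333333333,            2,            1,            1,            1,          0.5,            1
dist_river, 0.3333333333,          0.5,          0.5,            1,          0.5,          0.5,            2,            1,            1,            2,            1,            1
dist_lake,         0.25, 0.3333333333,          0.5,          0.5,         0.25, 0.3333333333,            2,            1,            1,            1,            1,            1
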