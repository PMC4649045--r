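section_id,plane,ray_id,ring_id,zone,area_um2,height_um,length_um,width_um,centroid_x_mm,centroid_y_mm,initiating,disappearing,edge_flag
disc_T1,tangential,1,,,1139.3,106,,10.75,3.071,2.6313,FALSE,FALSE,FALSE
disc_T1,tangential,2,,,3321,278.1,,11.94,1.4869,3.5363,FALSE,FALSE,FALSE
disc_T1,tangential,3,,,4448.8,306.8,,14.5,1.2446,3.36,FALSE,FALSE,FALSE
disc_T1,tangential,4,,,1740.8,152,,11.45,1.3749,3.7687,FALSE,FALSE,FALSE
disc_T1,tangential,5,,,1827.2,129,,14.16,1.9319,3.2157,FALSE,FALSE,FALSE
disc_T1,tangential,6,,,1657.8,97.8,,16.95,3.3642,2.6332,FALSE,FALSE,FALSE
disc_T1,tangential,7,,,1651.1,131.1,,12.59,1.8206,2.3125,FALSE,FALSE,FALSE
disc_T1,tangential,8,,,5290.9,237.6,,22.27,3.4421,2.6208,FALSE,FALSE,FALSE
disc_T1,tangential,9,,,1709.7,95.3,,17.94,2.7044,3.1918,FALSE,FALSE,FALSE
disc_T1,tangential,10,,,1518.4,91.9,,16.52,2.9103,2.2761,FALSE,FALSE,FALSE
disc_T1,tangential,11,,,2811.8,180.3,,15.6,3.9133,3.2058,FALSE,FALSE,FALSE
disc_T1,tangential,12,,,5173,277.2,,18.66,0.7811,0.8579,FALSE,FALSE,FALSE
disc_T1,tangential,13,,,3019.1,176.5,,17.11,0.5866,3.8986,FALSE,FALSE,FALSE
disc_T1,tangential,14,,,3133.5,177.6,,17.64,1.9925,0.6947,FALSE,FALSE,FALSE
disc_T1,tangential,15,,,2166.1,150.9,,14.35,3.0749,0.0632,FALSE,FALSE,FALSE
disc_T1,tangential,16,,,2385.3,191,,12.49,1.1603,3.558,FALSE,FALSE,FALSE
disc_T1,tangential,17,,,3070.8,195.2,,15.73,2.8206,3.337,FALSE,FALSE,FALSE
disc_T1,tangential,18,,,2931.9,214.4,,13.67,0.3334,2.5623,FALSE,FALSE,FALSE
disc_T1,tangential,19,,,5024.3,243.1,,20.67,0.3775,3.4956,FALSE,FALSE,FALSE
disc_T1,tangential,20,,,1169.7,115.9,,10.09,2.3447,2.3787,FALSE,FALSE,FALSE
disc_T1,tangential,21,,,2507.7,140.2,,17.89,1.6051,1.1986,FALSE,FALSE,FALSE
disc_T1,tangential,22,,,2905,271.2,,10.71,2.6039,3.3605,FALSE,FALSE,FALSE
disc_T1,tangential,23,,,1394.2,112.5,,12.39,2.4933,2.3953,FALSE,FALSE,FALSE
disc_T1,tangential,24,,,2520.4,253.3,,9.95,3.6993,2.8412,FALSE,FALSE,FALSE
core_C1,cross,1,1,early,5200,,310,16.77,2.0029,5.2619,TRUE,FALSE,FALSE
core_C1,cross,2,1,late,3100,,180,17.22,3.4929,15.8038,FALSE,FALSE,FALSE
core_C1,cross,3,2,early,4800,,290,16.55,2.5655,2.0371,TRUE,FALSE,FALSE
core_C1,cross,4,2,early,6100,,350,17.43,5.2098,1.6694,FALSE,FALSE,TRUE
core_C1,cross,5,3,late,2900,,170,17.06,2.7531,7.0102,TRUE,FALSE,FALSE
core_C1,cross,6,3,early,5500,,330,16.67,2.5559,13.9926,FALSE,FALSE,FALSE
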