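table,dose_mg,day,count,total_area,printed_average,consistent
total,40,1,11331,28.355,0.003,TRUE
total,40,1,4837,27.377,0.006,TRUE
total,40,1,5908,29.601,0.005,TRUE
total,40,7,2189,32.981,0.015,TRUE
total,40,7,5027,30.979,0.006,TRUE
total,40,30,5997,28.524,0.005,TRUE
total,40,30,11263,7.327,6.51E-04,TRUE
total,40,30,10501,9.992,9.52E-04,TRUE
total,40,30,10975,12,0.001,TRUE
total,40,30,10809,12.763,0.001,TRUE
total,60,1,3004,38.165,0.013,TRUE
total,60,7,8931,26.479,0.003,TRUE
total,60,7,11089,29.17,0.003,TRUE
total,60,30,4429,24.807,0.006,TRUE
total,60,30,3966,26.011,0.007,TRUE
total,60,30,5423,24.652,0.005,TRUE
total,60,30,11705,22.066,0.002,TRUE
total,60,30,20.033,20.033,0.002,FALSE
melanin,40,1,829,7.933,0.01,TRUE
melanin,40,7,3435,1.359,3.96E-04,TRUE
melanin,40,30,15042.2,9.3396,5.72E-04,FALSE
melanin,60,1,29149.67,7.457667,2.55E-04,FALSE
melanin,60,7,26562.25,7.48525,2.85E-04,FALSE
melanin,60,30,19434.6,7.6842,3.93E-04,FALSE
lipofuscin,40,1,3049,20.183,0.007,TRUE
lipofuscin,40,7,5914,16.148,0.003,TRUE
lipofuscin,40,30,8105.667,16.16333,3.32E-03,FALSE
lipofuscin,60,1,7958.333,23.78567,3.333E-03,FALSE
lipofuscin,60,7,9871.75,22.0595,2.25E-03,FALSE
lipofuscin,60,30,5415.2,24.3394,4.6E-03,FALSE
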