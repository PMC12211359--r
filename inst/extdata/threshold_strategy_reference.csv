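"model","ages","threshold","eligible_pct","events_pct","cost","qalys"
"soft","30-75",NA,0,17.22,2896.97,13.9445
"soft","30-75",20,25.4,15.49,3058.69,13.9995
"soft","30-75",19,26.9,15.38,3069.51,14.002
"soft","30-75",18,28.5,15.29,3082.78,14.0039
"soft","30-75",17,30.2,15.21,3099.47,14.0051
"soft","30-75",16,32,15.15,3118.27,14.0059
"soft","30-75",15,33.9,15.08,3137.52,14.007
"soft","30-75",14,36,15,3160.65,14.0078
"soft","30-75",13,38.3,14.94,3186.38,14.0083
"soft","30-75",12,40.8,14.89,3216.52,14.008
"soft","30-75",11,43.6,14.87,3252.31,14.0068
"soft","30-75",10,46.6,14.85,3292.01,14.0054
"hard","30-75",NA,0,17.42,2904.86,13.9412
"hard","30-75",15,19.6,16.1,3031.48,13.9846
"hard","30-75",14,21.3,15.92,3038.66,13.9893
"hard","30-75",13,23.1,15.77,3049.3,13.9932
"hard","30-75",12,25.1,15.61,3061.8,13.9974
"hard","30-75",11,27.3,15.46,3078.87,14.0007
"hard","30-75",10,29.7,15.32,3099.32,14.0038
"hard","30-75",9,32.6,15.19,3126.75,14.0058
"hard","30-75",8,35.7,15.08,3160.21,14.0071
"hard","30-75",7.5,37.5,15.04,3180.38,14.0072
"hard","30-75",7,39.4,15,3203.11,14.0071
"hard","30-75",6,43.6,14.92,3255.13,14.0065
"hard","30-75",5,48.6,14.91,3322.82,14.0034
"soft","30-59",NA,0,NA,2631.12,15.3115
"soft","30-59",20,10.4,NA,2738.66,15.3309
"soft","30-59",19,11.6,NA,2744.67,15.3334
"soft","30-59",18,12.9,NA,2753.4,15.3357
"soft","30-59",17,14.4,NA,2766.06,15.3376
"soft","30-59",16,16.1,NA,2780.29,15.3398
"soft","30-59",15,18,NA,2796.22,15.3423
"soft","30-59",14,20.2,NA,2816.21,15.3449
"soft","30-59",13,22.7,NA,2839.49,15.3476
"soft","30-59",12,25.5,NA,2868.64,15.3497
"soft","30-59",11,28.6,NA,2904.53,15.3515
"soft","30-59",10,32.1,NA,2946.04,15.3531
"soft","60-75",NA,0,NA,594.47,7.7303
"soft","60-75",20,76,NA,1027.76,7.7842
"soft","60-75",19,78.5,NA,1045.31,7.7848
"soft","60-75",18,81.1,NA,1062.6,7.7852
"soft","60-75",17,83.4,NA,1079.46,7.7855
"soft","60-75",16,85.6,NA,1095.5,7.7856
"soft","60-75",15,87.5,NA,1109.24,7.7858
"soft","60-75",14,89.4,NA,1122.76,7.7858
"soft","60-75",13,91.1,NA,1135.7,7.7858
"soft","60-75",12,92.7,NA,1147.44,7.7858
"soft","60-75",11,94.1,NA,1158.44,7.7856
"soft","60-75",10,95.5,NA,1168.64,7.7855
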