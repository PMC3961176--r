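pair,f,delta1_pct,delta2_pct,nb_pct,ae_pct
k_dA/k_dB,0,-0,-90,214.64436,214.64436
k_dA/k_dB,0.034482759,-3.1034483,-86.896552,234.98986,216.23629
k_dA/k_dB,0.068965517,-6.2068966,-83.793103,258.21806,217.97612
k_dA/k_dB,0.10344828,-9.3103448,-80.689655,284.98673,219.88589
k_dA/k_dB,0.13793103,-12.413793,-77.586207,316.16936,221.99449
k_dA/k_dB,0.17241379,-15.517241,-74.482759,352.95089,224.34254
k_dA/k_dB,0.20689655,-18.62069,-71.37931,396.97882,226.99358
k_dA/k_dB,0.24137931,-21.724138,-68.275862,450.60996,230.06635
k_dA/k_dB,0.27586207,-24.827586,-65.172414,517.32921,233.88702
k_dA/k_dB,0.31034483,-27.931034,-62.068966,602.48841,241.56462
k_dA/k_dB,0.34482759,-31.034483,-58.965517,714.64309,252.26284
k_dA/k_dB,0.37931034,-34.137931,-55.862069,867.83679,264.77794
k_dA/k_dB,0.4137931,-37.241379,-52.758621,1082.746,278.83116
k_dA/k_dB,0.44827586,-40.344828,-49.655172,1333.7927,288.45053
k_dA/k_dB,0.48275862,-43.448276,-46.551724,1309.4497,273.41141
k_dA/k_dB,0.51724138,-46.551724,-43.448276,1309.4497,273.41141
k_dA/k_dB,0.55172414,-49.655172,-40.344828,1333.7927,288.45053
k_dA/k_dB,0.5862069,-52.758621,-37.241379,1082.746,278.83116
k_dA/k_dB,0.62068966,-55.862069,-34.137931,867.83679,264.77794
k_dA/k_dB,0.65517241,-58.965517,-31.034483,714.64309,252.26284
k_dA/k_dB,0.68965517,-62.068966,-27.931034,602.48841,241.56462
k_dA/k_dB,0.72413793,-65.172414,-24.827586,517.32921,233.88702
k_dA/k_dB,0.75862069,-68.275862,-21.724138,450.60996,230.06635
k_dA/k_dB,0.79310345,-71.37931,-18.62069,396.97882,226.99358
k_dA/k_dB,0.82758621,-74.482759,-15.517241,352.95089,224.34254
k_dA/k_dB,0.86206897,-77.586207,-12.413793,316.16936,221.99449
k_dA/k_dB,0.89655172,-80.689655,-9.3103448,284.98673,219.88589
k_dA/k_dB,0.93103448,-83.793103,-6.2068966,258.21806,217.97612
k_dA/k_dB,0.96551724,-86.896552,-3.1034483,234.98986,216.23629
k_dA/k_dB,1,-90,-0,214.64436,214.64436
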