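n_avg,kind,scan,median_value,iqr_value,median_error,iqr_error
6,ventilation,1,0.179,0.134,0.016,0.008
6,ventilation,2,0.173,0.109,0.015,0.007
6,ventilation,3,0.191,0.124,0.017,0.008
6,ventilation,4,0.222,0.124,0.015,0.008
6,ventilation,5,0.215,0.122,0.015,0.008
6,ventilation,6,0.219,0.111,0.018,0.007
6,ventilation,7,0.224,0.121,0.017,0.007
6,ventilation,8,0.184,0.096,0.016,0.007
6,ventilation,9,0.221,0.124,0.014,0.007
6,ventilation,10,0.22,0.136,0.015,0.007
6,perfusion_amplitude,1,0.027,0.032,0.006,0.004
6,perfusion_amplitude,2,0.026,0.03,0.006,0.005
6,perfusion_amplitude,3,0.027,0.029,0.005,0.004
6,perfusion_amplitude,4,0.029,0.03,0.005,0.005
6,perfusion_amplitude,5,0.027,0.029,0.005,0.004
6,perfusion_amplitude,6,0.031,0.03,0.006,0.004
6,perfusion_amplitude,7,0.03,0.032,0.006,0.005
6,perfusion_amplitude,8,0.027,0.032,0.005,0.004
6,perfusion_amplitude,9,0.028,0.031,0.005,0.004
6,perfusion_amplitude,10,0.03,0.031,0.006,0.005
6,perfusion_timing,1,-56.32,116.19,56.91,44.98
6,perfusion_timing,2,-46.92,121.3,53.76,34.33
6,perfusion_timing,3,-75.36,125.06,49.15,29.15
6,perfusion_timing,4,-88.23,106.03,43.3,20.56
6,perfusion_timing,5,-68.33,119.2,44.5,22.96
6,perfusion_timing,6,-112.74,96.93,42.1,20.01
6,perfusion_timing,7,-121.8,116.77,47.8,23.78
6,perfusion_timing,8,-33.47,120.92,52.26,32.23
6,perfusion_timing,9,-99.76,110.71,40.38,16.69
6,perfusion_timing,10,-90.93,104.75,46.96,22.01
3,ventilation,1,0.181,0.137,0.041,0.018
3,ventilation,2,0.119,0.111,0.039,0.022
3,ventilation,3,0.155,0.123,0.038,0.017
3,ventilation,4,0.188,0.137,0.04,0.021
3,ventilation,5,0.212,0.121,0.037,0.017
3,ventilation,6,0.188,0.111,0.037,0.02
3,ventilation,7,0.194,0.126,0.038,0.02
3,ventilation,8,0.165,0.117,0.037,0.019
3,ventilation,9,0.181,0.118,0.037,0.018
3,ventilation,10,0.187,0.125,0.037,0.015
3,perfusion_amplitude,1,0.03,0.028,0.011,0.005
3,perfusion_amplitude,2,0.026,0.025,0.009,0.004
3,perfusion_amplitude,3,0.024,0.024,0.009,0.004
3,perfusion_amplitude,4,0.032,0.028,0.01,0.004
3,perfusion_amplitude,5,0.025,0.025,0.009,0.004
3,perfusion_amplitude,6,0.031,0.029,0.009,0.004
3,perfusion_amplitude,7,0.026,0.029,0.009,0.004
3,perfusion_amplitude,8,0.029,0.027,0.009,0.004
3,perfusion_amplitude,9,0.03,0.027,0.009,0.004
3,perfusion_amplitude,10,0.029,0.029,0.01,0.005
3,perfusion_timing,1,-16.8,166.8,101.23,122.89
3,perfusion_timing,2,-51.45,210.1,108.92,139.11
3,perfusion_timing,3,-13.12,203.71,115.07,167.17
3,perfusion_timing,4,-43.62,169.32,84.81,89.47
3,perfusion_timing,5,3.05,262.25,108.4,143.98
3,perfusion_timing,6,-11.94,152.92,79.92,97.81
3,perfusion_timing,7,-143.42,338.3,106.24,171.29
3,perfusion_timing,8,-29,152.23,84.79,114.43
3,perfusion_timing,9,-85.54,166.37,83.99,111.26
3,perfusion_timing,10,-25.74,211.35,94.6,113.9
1,ventilation,1,0.163,0.161,0.065,0.025
1,ventilation,2,0.108,0.154,0.066,0.023
1,ventilation,3,0.14,0.149,0.063,0.023
1,ventilation,4,0.176,0.159,0.068,0.028
1,ventilation,5,0.196,0.146,0.068,0.024
1,ventilation,6,0.178,0.138,0.063,0.027
1,ventilation,7,0.18,0.146,0.065,0.023
1,ventilation,8,0.148,0.14,0.06,0.022
1,ventilation,9,0.168,0.155,0.068,0.024
1,ventilation,10,0.178,0.14,0.059,0.02
1,perfusion_amplitude,1,0.043,0.035,0.021,0.006
1,perfusion_amplitude,2,0.04,0.033,0.022,0.006
1,perfusion_amplitude,3,0.04,0.033,0.021,0.005
1,perfusion_amplitude,4,0.046,0.037,0.023,0.006
1,perfusion_amplitude,5,0.041,0.034,0.021,0.006
1,perfusion_amplitude,6,0.044,0.036,0.021,0.005
1,perfusion_amplitude,7,0.04,0.034,0.021,0.006
1,perfusion_amplitude,8,0.045,0.037,0.021,0.006
1,perfusion_amplitude,9,0.044,0.036,0.021,0.006
1,perfusion_amplitude,10,0.042,0.035,0.021,0.006
1,perfusion_timing,1,-13.3,319.46,198.73,209.77
1,perfusion_timing,2,-44.28,397.53,232.63,221.85
1,perfusion_timing,3,-10.86,410.09,228.52,232.49
1,perfusion_timing,4,-47.53,336.23,204.95,217.5
1,perfusion_timing,5,11.33,422.12,229.55,236.33
1,perfusion_timing,6,-24.21,313.16,187.02,211.93
1,perfusion_timing,7,-49.67,445.3,230.81,237.73
1,perfusion_timing,8,-25.45,306.63,179.49,210.06
1,perfusion_timing,9,-12.93,329.83,189.53,206.17
1,perfusion_timing,10,32.96,343.75,201.27,212
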