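ferret,method,internal_sd,criterion_bias_mean,criterion_bias_sd,guess_rate_pct,reference_level,trial_shift_1,trial_shift_2,simsim_r2_pcmax,simsim_r2_hits,simsim_r2_fa,expsim_r2_pcmax,expsim_r2_hits,expsim_r2_fa
F1_35,limits,10.54,1.8,1.52,1,12.54,2,1,0.93,0.87,0.84,0.90,0.82,0.74
F1_55,limits,11.83,1.48,0.02,1,31.55,2,1,0.86,0.78,0.74,0.81,0.72,0.62
F2,limits,9.2,3.78,3.12,1,37.35,2,1.5,0.90,0.77,0.73,0.94,0.90,0.87
F3,limits,11.29,1.03,0.03,5,39.46,2.5,2,0.86,0.79,0.72,0.86,0.70,0.31
F4,limits,11.00,1.05,1.80,5,29.86,2,1.5,0.91,0.80,0.79,0.81,0.38,0.62
F5,limits,7.24,1.85,0.84,1.3,30.30,2,1,0.94,0.92,0.84,0.92,0.76,0.28
F1_35,constant,11,2.98,0.34,1,12,2.5,1,0.92,0.95,NA,0.80,0.88,NA
F1_55,constant,11.8,3.40,0.07,1,32.76,3,2.5,0.88,0.93,NA,0.81,0.87,NA
F2,constant,8.07,3.62,0.11,1,37.39,2,1.5,0.91,0.96,NA,0.68,0.85,NA
F3,constant,11.86,4.19,0.06,2,40.51,3.5,3,0.90,0.95,NA,0.90,0.86,NA
F4,constant,10.50,3.20,1.84,1,35.14,2,1.5,0.89,0.93,NA,0.83,0.87,NA
F5,constant,11.09,2.24,0.89,2,26.29,2,1.5,0.85,0.92,NA,0.58,0.74,NA
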