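scene,method,initial,screened,mismatches,rate_pct
low_snr,sift_ransac,468,38,16,57.89
low_snr,orb_ransac,511,51,23,54.90
low_snr,proposed,556,73,7,90.41
high_dynamic_range,sift_ransac,569,55,34,38.18
high_dynamic_range,orb_ransac,391,35,27,22.86
high_dynamic_range,proposed,771,68,2,97.06
starfield,sift_ransac,387,15,15,0.00
starfield,orb_ransac,499,19,14,26.32
starfield,proposed,486,97,0,100.00
medical,sift_ransac,450,28,17,39.29
medical,orb_ransac,411,34,22,35.29
medical,proposed,622,150,14,90.67
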