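subject,sst_tif_val,sst_tif_test,sst_fused_val,sst_fused_test,cst_tif_val,cst_tif_test,cst_fused_val,cst_fused_test
1,93.03,68.33,92.66,79.72,86.47,70.41,88.79,83.43
2,81.11,32.86,74.81,38.16,57.61,52.63,62.29,56.14
3,90.37,52.38,90.37,69.23,79.55,72.05,82.18,88.82
4,85.84,50.44,86.61,56.14,77.50,60.34,81.00,60.34
5,60.56,30.43,60.57,37.32,67.35,59.15,56.89,57.93
6,83.96,40.47,86.73,41.86,71.90,57.28,76.16,68.93
7,84.91,33.21,86.03,35.02,75.50,51.52,74.66,60.61
8,78.72,45.76,90.85,67.53,73.88,61.64,86.91,77.36
9,95.31,76.52,95.27,79.92,93.96,84.21,94.50,91.45
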