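"case_id","cpg_1","cpg_2","cpg_3","cpg_4","cpg_5","cpg_6","cpg_7","cpg_8","cpg_9","cpg_10","cpg_11","cpg_12","cpg_13","cpg_14","cpg_15","cpg_16","cpg_17","cpg_18","cpg_19","cpg_20","cpg_21","cpg_22","cpg_23","cpg_24"
"case_0001",1.16,1.94,0.3,0.46,0.19,1.04,0.53,0.03,4.09,1.65,0.46,1.02,0.41,0.5,0.78,0.71,1.74,0.62,1.44,3.53,2.95,1.69,1.94,0.26
"case_0002",0.02,1.19,0.17,0.61,0.73,0.94,0.74,0.6,1.3,0.57,0.53,0.35,6.21,1.38,2.8,4.92,0.8,3.83,2.6,0.53,1.99,1.16,0.21,0.33
"case_0003",0.19,3.15,1.26,2.47,0.56,0.57,0.8,0.05,0.99,2.93,0.23,1.62,1.27,2.11,1.16,1.22,0.2,0.52,0.92,2.17,0.64,1.9,1.7,2.55
"case_0004",0.07,2.58,2.42,3.9,0.59,0.91,1.81,1.25,2.21,1.81,1.95,0.3,2.54,1.53,0.05,0.08,1.52,1.69,2.46,2.66,0.62,3.46,1.1,1.06
"case_0005",37.7,0.16,44.22,52.76,88.87,94.24,72.24,81.86,80.95,39.1,49.22,0.29,3.29,0.7,38.33,0.27,25.81,31.4,0.81,1.43,60.95,51.11,64.97,2.16
"case_0006",0.78,0.46,0.52,0.26,1.72,4.26,0.29,0.43,0.14,2.15,0.47,1.11,4.34,0.15,2.1,0.68,0.73,2.24,0.42,0.57,0.35,0.9,4.21,1.18
"case_0007",0.99,0.46,1.49,1.89,1.78,0.1,0.1,0.21,1.15,0.33,0.5,0.33,0.81,4.01,0.07,1.35,1.76,0.11,0.98,1.56,1.47,0.37,2.64,0.23
"case_0008",0.98,0.14,0.21,0.83,0.3,0.27,1.56,0.88,0.98,0.71,0.82,2.71,2.06,2.15,0.95,0.55,0.46,2.09,2.57,1.46,4.75,0.66,1.03,4.73
"case_0009",1.2,1.37,4.73,0.48,4.44,1.06,0.46,0.44,1.78,2.53,1.27,0.35,2.09,2.39,0.37,1.97,0.07,0.14,1.19,2.26,0.77,0.25,0.55,0.35
"case_0010",0.46,0.15,0.12,1.11,0.32,1.8,1.88,0.16,1.28,0.72,0.11,1.01,2.64,0.15,0.47,1.48,0.17,0.27,0.56,0.6,0.87,1.29,0.64,4.7
"case_0011",2.47,55.05,3.31,0.97,63.08,46.95,1.14,0.72,44.49,50.67,21.18,74.48,60.07,0.12,0.09,46.76,24.47,74.52,59.46,77.98,2.59,47.06,53.1,2.08
"case_0012",0.57,73.55,1.95,0.67,84.98,71.09,1.09,77.76,0.42,0.15,85.56,1.26,2.74,86.9,1.03,1.54,73.82,2.45,1.98,0.53,3.71,0.49,0.73,49
"case_0013",1.34,0.62,3.04,0.59,2.24,1,2.53,1.74,2.91,1.02,2.69,1.62,0.34,2.64,1.2,0.34,0.89,1.29,5.42,0.16,2.22,0.53,0.35,0.51
"case_0014",3.54,1.29,1.97,2.65,3.25,3.03,0.86,2.14,1.28,0.86,4.59,3.04,0.61,0.8,1.21,0.86,3.03,1.31,2.07,2.84,2.1,1.75,3.07,0.32
"case_0015",1.81,0.26,1.99,1.34,3.51,0.03,3.23,0.08,2.83,0.5,1.25,0.9,0.88,0.7,1.18,1.18,2.59,1.01,0.14,1.08,0.55,1.4,0.48,0.84
"case_0016",0.81,1.36,1.54,1.31,0.66,0.41,0.7,1.96,1.23,0.62,1.5,3.98,0.69,0.53,2.47,3.18,0.94,0.6,1.71,2.41,2.08,2.74,0.79,3.02
"case_0017",2.47,0.27,0.27,0.56,0.14,0.54,0.51,2.13,0.38,1.98,0.4,0.51,2.51,0.5,2.2,2.25,1.72,0.17,0.94,1,0.94,0.6,0.35,1.18
"case_0018",1.22,1.3,0.66,0.13,4.76,0.03,3.34,2.2,0.43,1.63,0.51,1.43,2.2,0.42,0.5,1.48,4.3,0.57,2.15,0.5,0.26,1.24,2.3,0.44
"case_0019",32.82,76.33,93.7,2.82,68.53,74.95,52.6,3.03,67.94,59.34,44.45,66.41,58.17,0.29,2.18,68.48,0.5,1.07,40.6,1.93,3.68,0.17,3.34,3.54
"case_0020",54.74,27.51,52.2,55.89,76.31,1.1,2.99,3,0.81,0.14,54.25,0.22,0.06,87.9,1.03,0.37,1.19,1.79,41.13,96.62,3.27,1.43,0.97,2.07
"case_0021",0.07,2.95,0.07,6.24,1.36,0.36,1.24,4,0.25,1.57,3.38,1.98,0.29,2.04,0.89,0.93,3.27,0.58,1.47,0.28,2.87,0.74,0.8,0.78
"case_0022",86.33,77.93,60.92,48.56,72.74,53.91,43.83,57.59,23.82,85.64,74.89,80.17,36.03,42.27,64.24,83.89,79.92,48.77,42.62,0.42,25.82,35.42,66.14,59.19
"case_0023",0.24,48.42,0.12,19.28,81.16,79.11,1.37,3.22,24.2,0.47,68.04,1.2,0.16,0.72,0.16,0.65,1.82,0.4,0.46,37.09,0.67,1.3,0.53,4.17
"case_0024",0.1,0.39,0.35,0.71,0.09,3.01,0.97,2.11,2.68,0.22,1.5,1.4,0.52,0.43,0.63,0.07,0.29,0.18,2.4,0.46,3.44,2.62,0.57,1.79
"case_0025",38.95,30.97,48.28,65.28,2.28,0.57,0.92,90.08,80.5,73.84,62.95,0.26,1.37,0.96,88.29,3.76,78.34,78.56,0.2,53.55,1.33,1.42,87.35,1.13
"case_0026",0.99,0.64,0.94,1.23,0.02,0.08,0.45,1.72,0.35,0.15,2.97,0.87,1.43,0.34,2.62,0.19,1.5,2.71,0.56,0.6,0.52,0.12,0.5,1.08
"case_0027",1.97,91.92,60.94,2.72,2.97,0.37,1.46,24.17,0.75,94.98,2.71,0.67,1.87,0.48,0.31,4.34,0.16,0.46,0.38,0.91,3.17,0.52,0.71,2.44
"case_0028",1.21,1.81,1.45,1.11,3.16,2.5,0.18,1.58,0.65,3.81,0.41,0.96,0.37,1.16,0.66,2.06,0.53,0.83,0.42,0.21,0.34,0.3,1.07,0.86
"case_0029",2.68,2.43,0.47,0.62,0.64,0.72,0.56,0.62,0.03,1.62,0.6,2.03,2.22,1.26,0.41,0.95,0.59,1.64,0.36,1.03,3.29,1.06,0.81,3.63
"case_0030",0.78,0.3,2.81,1.77,0.3,1.33,0.36,3.21,3.01,0.78,1.56,3.26,3.02,1.27,0.52,0.09,1.89,0.65,1.42,3.4,1.81,0.87,0.45,3.7
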