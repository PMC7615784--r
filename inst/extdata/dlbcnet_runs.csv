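run,class,accuracy,sensitivity,precision,specificity,f1
1,eosinophil,94.31,91.00,95.41,86.54,93.15
1,lymphocyte,98.74,99.76,99.95,99.84,99.85
1,monocyte,95.77,87.66,99.97,99.91,93.41
1,neutrophil,93.90,93.79,95.41,87.19,94.59
2,eosinophil,95.76,92.83,96.74,90.46,94.74
2,lymphocyte,97.63,100.00,100.00,100.00,100.00
2,monocyte,94.33,86.55,99.97,99.91,92.78
2,neutrophil,92.05,93.95,94.40,84.83,94.17
3,eosinophil,96.26,92.28,97.58,92.72,94.86
3,lymphocyte,97.42,100.00,99.97,99.92,99.99
3,monocyte,94.41,87.66,99.97,99.91,93.41
3,neutrophil,91.68,94.51,93.95,83.89,94.23
4,eosinophil,95.50,91.80,96.74,90.36,94.20
4,lymphocyte,97.53,99.60,100.00,100.00,99.81
4,monocyte,94.56,87.50,99.97,99.91,93.32
4,neutrophil,91.55,93.15,93.98,83.75,93.56
5,eosinophil,95.68,92.52,96.74,90.42,94.58
5,lymphocyte,97.63,100.00,100.00,100.00,100.00
5,monocyte,94.35,86.54,100.00,100.00,92.79
5,neutrophil,91.96,93.95,94.27,84.53,94.11
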