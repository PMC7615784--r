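class,accuracy,sensitivity,precision,specificity,f1
eosinophil,95.50,92.09,96.64,90.16,94.31
lymphocyte,97.79,99.87,99.98,99.95,99.93
monocyte,94.68,87.18,99.98,99.93,93.14
neutrophil,92.23,93.87,94.40,84.84,94.13
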