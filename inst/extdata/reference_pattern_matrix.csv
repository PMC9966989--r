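item,ML1,ML2,ML3,ML4,ML5
Q01,0,0.86,0,0,0
Q02,0,0.88,0,0,0
Q03,0,0.91,0,0,0
Q04,0,0,0.86,0,0
Q05,0,0,0.87,0,0
Q06,0,0,0.70,0,0
Q07,0,0,0,0.81,0
Q08,0,0,0,0.84,0
Q09,0,0,0,0.52,0
Q10,0.36,0,0,0,0
Q11,0.74,0,0,0,0
Q12,0.65,0,0,0,0
Q13,0.71,0,0,0,0
Q14,0.42,0,0,0,0
Q15,0.57,0,0,0,0
Q16,0.69,0,0,0,0
Q17,0.62,0,0,0,0
Q18,0.59,0,0,0,0
Q19,0,0,0,0,0.34
Q20,0,0,0,0,0.41
Q21,0,0,0,0,0.52
Q22,0,0,0,0,0.60
Q23,0,0,0,0,0.54
Q24,0,0,0,0,0.50
Q25,0,0,0,0,0.34
Q26,0,0,0,0,0.32
Q27,0.32,0,0,0,0
Q28,0,0,0,0,0.32
Q29,0.29,0,0,0,0
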