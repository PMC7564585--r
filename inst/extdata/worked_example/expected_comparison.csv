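protein,log2_fold_change,p_value,category
P01,0.048809118511687198,0.65192313989717421,UNCHANGED
P02,-1.8585819609816798,0.00013740520805278578,DOWN
P03,2.0112134516301245,0.00019012356474177211,UP
P04,0.30753161090029035,0.33155445638817255,UNCHANGED
P06,0.43332099158293391,0.41625387555678262,UNCHANGED
P10,1.049900315181225,4.0307788748137434e-05,UP
P11,0.051995639320113328,0.73222777177557041,UNCHANGED
P12,0.12321556434643026,0.32813943882555047,UNCHANGED
P13,0.051380252633570732,0.65377253199307372,UNCHANGED
P14,0.15597974609909673,0.37503411949541171,UNCHANGED
P15,0.050420248227685219,0.40819189756681412,UNCHANGED
P16,0.19800621120053158,0.1983226985322851,UNCHANGED
P17,0.052698937754594652,0.78871178912080653,UNCHANGED
P18,0.048303309412189251,0.52082379922983868,UNCHANGED
P19,0.043357902158754819,0.86237823764708843,UNCHANGED
P20,0.049760194425095543,0.26626174172356115,UNCHANGED
P07,,,UNIQUE_CONTROL
P08,,,UNIQUE_TREATMENT
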