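state,protein
control,P01
control,P02
control,P03
control,P04
control,P07
control,P10
control,P11
control,P12
control,P13
control,P14
control,P15
control,P16
control,P17
control,P18
control,P19
control,P20
treatment,P01
treatment,P02
treatment,P03
treatment,P04
treatment,P06
treatment,P08
treatment,P10
treatment,P11
treatment,P12
treatment,P13
treatment,P14
treatment,P15
treatment,P16
treatment,P17
treatment,P18
treatment,P19
treatment,P20
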