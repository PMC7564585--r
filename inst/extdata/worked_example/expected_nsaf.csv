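state,replicate,protein,nsaf
control,1,P01,0.061086437665803503
control,1,P02,0.20362145888601166
control,1,P03,0.011453707062338156
control,1,P04,0.0244345750663214
control,1,P05,0.0050905364721502916
control,1,P06,0.033936909814335274
control,1,P07,0.034906535809030567
control,1,P09,0.0038179023541127189
control,1,P10,0.050905364721502915
control,1,P11,0.027488896949611572
control,1,P12,0.091629656498705248
control,1,P13,0.10471960742709172
control,1,P14,0.018795826974093384
control,1,P15,0.06941640643841307
control,1,P16,0.061086437665803503
control,1,P17,0.028507004244041633
control,1,P18,0.064679757528497819
control,1,P19,0.0064301513332424738
control,1,P20,0.10181072944300583
control,2,P01,0.072831164854098893
control,2,P02,0.2225396703875244
control,2,P03,0.015173159344603938
control,2,P04,0.024277054951366298
control,2,P05,0.0050577197815346456
control,2,P06,0.0033718131876897639
control,2,P07,0.039016695457552979
control,2,P09,0.0037932898361509844
control,2,P10,0.047205384627656694
control,2,P11,0.024277054951366298
control,2,P12,0.10621211541222755
control,2,P13,0.095374144451796164
control,2,P14,0.023343322068621442
control,2,P15,0.066210149867362622
control,2,P16,0.060692637378415751
control,2,P17,0.024277054951366298
control,2,P18,0.067832947658229364
control,2,P19,0.0095830480071182767
control,2,P20,0.096096675849158264
control,3,P01,0.065236838353889631
control,3,P02,0.17791865005606264
control,3,P03,0.011119915628503915
control,3,P04,0.011861243337070844
control,3,P05,0.0049421847237795177
control,3,P06,0.039537477790236142
control,3,P07,0.02965310834267711
control,3,P09,0.02965310834267711
control,3,P10,0.052716637053648194
control,3,P11,0.02965310834267711
control,3,P12,0.088959325028031319
control,3,P13,0.11014011670137212
control,3,P14,0.018248066672416682
control,3,P15,0.070089165173600435
control,3,P16,0.05930621668535422
control,3,P17,0.031629982232188915
control,3,P18,0.05930621668535422
control,3,P19,0.0062427596510899169
control,3,P20,0.10378587919936987
treatment,1,P01,0.070489506996823284
treatment,1,P02,0.053401141664260063
treatment,1,P03,0.048061027497834058
treatment,1,P04,0.025632547998844832
treatment,1,P05,0.0053401141664260066
treatment,1,P06,0.028480608887605369
treatment,1,P08,0.040779053634525865
treatment,1,P10,0.10680228332852013
treatment,1,P11,0.028836616498700434
treatment,1,P12,0.11214239749494613
treatment,1,P13,0.10985377713790642
treatment,1,P14,0.024646680768120034
treatment,1,P15,0.072819738633081901
treatment,1,P16,0.064081369997112086
treatment,1,P17,0.029904639331985637
treatment,1,P18,0.067850862349883384
treatment,1,P19,0.0067454073681170613
treatment,1,P20,0.10413222624530713
treatment,2,P01,0.06238618719497184
treatment,2,P02,0.06238618719497184
treatment,2,P03,0.054587913795600351
treatment,2,P04,0.024954474877988735
treatment,2,P05,0.010397697865828639
treatment,2,P06,0.03465899288609546
treatment,2,P08,0.04537177250543406
treatment,2,P10,0.10051107936967685
treatment,2,P11,0.03119309359748592
treatment,2,P12,0.093579280792457753
treatment,2,P13,0.11586006193351912
treatment,2,P14,0.019195749906145181
treatment,2,P15,0.073729130321330341
treatment,2,P16,0.06238618719497184
treatment,2,P17,0.033272633170651648
treatment,2,P18,0.06238618719497184
treatment,2,P19,0.00656696707315493
treatment,2,P20,0.10657640312474355
treatment,3,P01,0.073131792522267633
treatment,3,P02,0.050785967029352529
treatment,3,P03,0.049516317853618715
treatment,3,P04,0.024377264174089214
treatment,3,P05,0.0050785967029352529
treatment,3,P06,0.040628773623482023
treatment,3,P08,0.049862585810637031
treatment,3,P10,0.10495766519399523
treatment,3,P11,0.024377264174089214
treatment,3,P12,0.1066505307616403
treatment,3,P13,0.095767823541064764
treatment,3,P14,0.023439677090470398
treatment,3,P15,0.066483447747516036
treatment,3,P16,0.081257547246964046
treatment,3,P17,0.024377264174089214
treatment,3,P18,0.068112944015837507
treatment,3,P19,0.0096226042792457427
treatment,3,P20,0.10157193405870506
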