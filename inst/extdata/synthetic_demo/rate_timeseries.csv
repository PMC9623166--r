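sample,time_h,value
S01,24,13.0170399845403
S01,48,24.9648329849268
S01,72,36.9810231134679
S01,96,48.9626976281362
S01,130,65.9550946335046
S01,154,77.9832602945912
S02,24,12.9550541765601
S02,48,25.0106065544878
S02,72,36.9635704954002
S02,96,49.0617760222291
S02,130,66.0584420014205
S02,154,77.9688757471656
S03,24,13.0997348168873
S03,48,25.0355571252533
S03,72,37.0092702642157
S03,96,48.9859117492655
S03,130,66.0054387773314
S03,154,77.9457131264884
S04,24,13.0099880443726
S04,48,24.860992965486
S04,72,36.9652123872665
S04,96,49.1037699952508
S04,130,66.0395111359483
S04,154,78.0244925397119
S05,24,12.9828366887509
S05,48,24.969330608544
S05,72,36.9156538683355
S05,96,48.9693607244591
S05,130,66.0038179016022
S05,154,77.9673607936884
S06,24,13.0274834946562
S06,48,24.9579198127689
S06,72,37.0016498967851
S06,96,49.0262074853968
S06,130,65.9136197944102
S06,154,77.9861067736624
S07,24,13.0379335807563
S07,48,24.97353275724
S07,72,36.9607825764979
S07,96,49.0339424413144
S07,130,66.0947999991992
S07,154,78.0009408149844
S08,24,12.9506904549924
S08,48,24.9802572391971
S08,72,37.0654257652765
S08,96,49.0477380005855
S08,130,65.8933460584516
S08,154,78.0534484863063
S09,24,13.009990930877
S09,48,24.9332234441948
S09,72,37.0321390971901
S09,96,48.9247234870891
S09,130,65.9600709357331
S09,154,78.0582059402253
S10,24,13.0941895944473
S10,48,25.0247292249948
S10,72,36.9817674155075
S10,96,49.0810311525452
S10,130,66.0583162464572
S10,154,77.948028630147
S11,24,13.0060069542037
S11,48,24.9093811574903
S11,72,37.0075791491815
S11,96,48.9440389497726
S11,130,66.0000954103175
S11,154,78.0594259247155
S12,24,12.9879524220049
S12,48,24.9749796907042
S12,72,36.9802379321581
S12,96,48.9602365378535
S12,130,66.0269980543162
S12,154,78.074446564525
S13,24,12.9653116781885
S13,48,24.9116585471322
S13,72,37.0311267982767
S13,96,49.1008338174913
S13,130,66.0070466609302
S13,154,78.0812831816971
S14,24,12.9775137563318
S14,48,25.0214927071353
S14,72,37.0490971806586
S14,96,48.9647315662211
S14,130,65.9690558068183
S14,154,77.9073589036596
S15,24,12.9068933141557
S15,48,25.0569903466417
S15,72,37.0158813363321
S15,96,49.0699929637776
S15,130,66.1118812983416
S15,154,77.9715045475783
S16,24,13.0360322518452
S16,48,25.0249952767976
S16,72,36.9712455561811
S16,96,48.9923202582067
S16,130,65.9133404194708
S16,154,77.9139124164445
S17,24,12.9809685369215
S17,48,24.9812535523807
S17,72,36.9139462191119
S17,96,49.0175238960494
S17,130,65.930796995723
S17,154,77.9905829835289
S18,24,13.0400635062892
S18,48,25.0142228353752
S18,72,36.9243601507854
S18,96,49.003731891276
S18,130,66.1130372431762
S18,154,78.0030997041568
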