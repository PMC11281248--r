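wavelength_nm,collagen3,hbo2,hb,water,fat
680,0.1,0.174493,1.012797,0.015,0.03
685,0.103103,0.176471,0.96668,0.015,0.03
690,0.106207,0.178709,0.925018,0.015,0.03
695,0.10931,0.18124,0.888785,0.015,0.03
700,0.112414,0.184099,0.859309,0.015,0.03
705,0.115517,0.187324,0.838206,0.015,0.03
710,0.118621,0.190957,0.827187,0.015,0.03
715,0.121724,0.195044,0.82772,0.015,0.03
720,0.124828,0.199633,0.840569,0.015,0.03
725,0.127931,0.204775,0.865276,0.015,0.03
730,0.131035,0.210524,0.899723,0.015,0.03
735,0.134138,0.216937,0.939947,0.015,0.03
740,0.137242,0.22407,0.980326,0.015,0.03
745,0.140347,0.23198,1.014217,0.015,0.03
750,0.143452,0.240721,1.03497,0.015,0.03
755,0.14656,0.250344,1.037099,0.015,0.03
760,0.149671,0.260897,1.017356,0.015,0.03
765,0.152788,0.272416,0.975376,0.015,0.03
770,0.155916,0.284929,0.913745,0.015,0.03
775,0.159063,0.298452,0.837454,0.015,0.03
780,0.162242,0.312984,0.752893,0.015,0.03
785,0.165475,0.328508,0.66667,0.015,0.030001
790,0.168794,0.344988,0.584551,0.015,0.030003
795,0.17225,0.362369,0.510733,0.015,0.030009
800,0.175918,0.380577,0.447568,0.015001,0.030023
805,0.179906,0.399519,0.395682,0.015002,0.030057
810,0.184369,0.419084,0.354382,0.015005,0.030134
815,0.189516,0.43915,0.32216,0.01501,0.030299
820,0.195628,0.459579,0.297179,0.015019,0.030633
825,0.203069,0.480229,0.277638,0.015038,0.031272
830,0.212291,0.500954,0.261992,0.015073,0.032426
835,0.223841,0.521604,0.24904,0.015137,0.034394
840,0.238349,0.542035,0.237916,0.015251,0.037557
845,0.256515,0.562103,0.228043,0.015452,0.042345
850,0.279062,0.581674,0.21905,0.015794,0.04915
855,0.306695,0.60062,0.210715,0.016367,0.05821
860,0.34002,0.618819,0.202906,0.017302,0.069466
865,0.379464,0.636161,0.195543,0.018794,0.082435
870,0.425188,0.652543,0.188579,0.021119,0.096175
875,0.476992,0.667871,0.181981,0.024658,0.109404
880,0.534243,0.682061,0.175724,0.029917,0.120936
885,0.595835,0.69504,0.16979,0.037546,0.130736
890,0.660178,0.706748,0.164161,0.048347,0.142083
895,0.725241,0.717137,0.15882,0.063269,0.164797
900,0.788652,0.726174,0.153754,0.083373,0.217223
905,0.847844,0.733842,0.148947,0.109777,0.321209
910,0.900232,0.740141,0.144387,0.143569,0.48531
915,0.943427,0.745091,0.14006,0.185676,0.683083
920,0.97543,0.748727,0.135955,0.236727,0.848792
925,0.994817,0.751105,0.132061,0.296884,0.90821
930,1.000863,0.752299,0.128367,0.365697,0.828477
935,0.993605,0.752396,0.124861,0.441973,0.642996
940,0.973839,0.751499,0.121536,0.523718,0.426716
945,0.943033,0.749723,0.118381,0.608146,0.246343
950,0.903189,0.747188,0.115388,0.69179,0.129463
955,0.856654,0.744021,0.112548,0.770709,0.068618
960,0.80592,0.740351,0.109854,0.840776,0.042716
965,0.753421,0.736303,0.107298,0.898035,0.033585
970,0.70136,0.731998,0.104873,0.939063,0.030886
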