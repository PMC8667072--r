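protein1 protein2 combined_score
g00001 g00002 403
g00001 g00003 625
g00001 g00007 594
g00001 g00010 384
g00001 g00012 245
g00001 g00014 529
g00001 g00015 338
g00001 g00016 564
g00001 g00018 348
g00001 g00024 236
g00001 g00029 607
g00001 g00032 163
g00001 g00033 559
g00001 g00035 417
g00001 g00036 439
g00001 g00039 384
g00001 g00045 321
g00001 g00048 332
g00002 g00003 657
g00002 g00004 466
g00002 g00005 365
g00002 g00007 272
g00002 g00008 234
g00002 g00011 669
g00002 g00020 207
g00002 g00031 334
g00002 g00034 547
g00002 g00038 417
g00002 m001 563
g00003 g00004 366
g00003 g00005 336
g00003 g00008 378
g00003 g00012 354
g00003 g00013 348
g00003 g00016 445
g00003 g00023 509
g00003 g00040 631
g00003 g00048 166
g00004 g00006 681
g00004 g00019 319
g00004 g00044 377
g00005 g00006 271
g00005 g00009 660
g00005 g00011 377
g00005 g00014 265
g00005 g00015 155
g00005 g00030 445
g00005 g00033 352
g00005 g00043 270
g00006 g00009 679
g00006 g00010 571
g00006 g00019 506
g00006 g00021 400
g00006 g00022 408
g00006 g00025 362
g00006 g00026 677
g00006 g00028 217
g00006 g00049 661
g00007 g00021 480
g00008 g00025 282
g00008 g00034 401
g00008 g00041 301
g00009 g00047 521
g00010 g00013 268
g00011 g00018 167
g00011 g00024 214
g00011 g00029 480
g00011 g00032 583
g00011 g00039 414
g00011 m010 352
g00012 g00023 152
g00012 g00031 695
g00012 g00042 514
g00012 g00046 418
g00013 g00027 447
g00014 g00017 664
g00015 g00020 681
g00015 g00028 490
g00015 g00037 446
g00015 g00042 383
g00015 g00047 360
g00015 g00049 593
g00016 g00017 284
g00016 g00038 251
g00016 g00040 278
g00016 m007 606
g00017 g00026 517
g00017 g00027 427
g00019 g00022 637
g00021 g00043 618
g00022 m008 524
g00026 m002 405
g00027 g00030 565
g00027 g00046 290
g00029 g00037 479
g00029 m006 366
g00031 g00035 305
g00032 g00036 446
g00032 m005 278
g00034 g00041 466
g00035 g00050 479
g00036 g00044 469
g00036 m003 517
g00037 m009 338
g00041 g00045 413
g00041 m004 586
g00047 g00050 263
m001 m002 946
m001 m003 987
m001 m004 983
m001 m005 944
m001 m006 911
m001 m008 953
m001 m009 932
m001 m010 934
m002 m003 955
m002 m004 913
m002 m005 974
m002 m006 948
m002 m008 995
m002 m009 991
m002 m010 972
m003 m004 982
m003 m005 904
m003 m006 986
m003 m007 975
m003 m008 937
m003 m009 950
m003 m010 999
m004 m005 989
m004 m006 991
m004 m007 908
m004 m008 933
m004 m009 931
m004 m010 993
m005 m006 902
m005 m007 939
m005 m008 908
m005 m009 904
m005 m010 938
m006 m007 907
m006 m008 947
m006 m010 907
m007 m008 913
m007 m009 934
m007 m010 927
m008 m009 984
m009 m010 918
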