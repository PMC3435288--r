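destination,origin,country,phi,relative_phi
Melbourne,Busan,KOR,0.245,94.601
Melbourne,Kaohsiung,TWN,0.227,87.532
Melbourne,Keelung,TWN,0.075,28.912
Melbourne,Damietta,EGY,0.039,14.925
Melbourne,Colombo,LKA,0.021,8.025
Melbourne,Jeddah,SAU,0.019,7.157
Melbourne,Valencia,ESP,0.018,6.916
Melbourne,Ulsan,KOR,0.017,6.510
Melbourne,Port Said,EGY,0.011,4.160
Melbourne,Barcelona,ESP,0.007,2.569
Botany Bay,Kaohsiung,TWN,0.159,61.473
Botany Bay,Busan,KOR,0.158,61.020
Botany Bay,Keelung,TWN,0.053,20.370
Botany Bay,Damietta,EGY,0.025,9.702
Botany Bay,Colombo,LKA,0.013,5.029
Botany Bay,Jeddah,SAU,0.012,4.704
Botany Bay,Valencia,ESP,0.012,4.593
Botany Bay,Port Said,EGY,0.007,2.673
Botany Bay,Barcelona,ESP,0.005,1.737
Botany Bay,Ulsan,KOR,0.004,1.500
Brisbane,Busan,KOR,0.160,61.541
Brisbane,Kaohsiung,TWN,0.158,61.098
Brisbane,Keelung,TWN,0.052,20.153
Brisbane,Damietta,EGY,0.023,9.043
Brisbane,Colombo,LKA,0.012,4.453
Brisbane,Jeddah,SAU,0.010,3.715
Brisbane,Valencia,ESP,0.009,3.388
Brisbane,Port Said,EGY,0.005,2.084
Brisbane,Gwangyang,KOR,0.004,1.611
Brisbane,Ulsan,KOR,0.004,1.497
Bell Bay,Busan,KOR,0.084,32.346
Bell Bay,Kaohsiung,TWN,0.070,27.181
Bell Bay,Keelung,TWN,0.023,8.947
Bell Bay,Damietta,EGY,0.012,4.681
Bell Bay,Ulsan,KOR,0.010,3.849
Bell Bay,Colombo,LKA,0.007,2.511
Bell Bay,Jeddah,SAU,0.006,2.307
Bell Bay,Valencia,ESP,0.006,2.234
Bell Bay,Port Said,EGY,0.003,1.274
Bell Bay,Barcelona,ESP,0.002,0.803
Fremantle,Busan,KOR,0.051,19.612
Fremantle,Kaohsiung,TWN,0.042,16.364
Fremantle,Damietta,EGY,0.012,4.653
Fremantle,Keelung,TWN,0.012,4.614
Fremantle,Valencia,ESP,0.009,3.369
Fremantle,Colombo,LKA,0.008,2.917
Fremantle,Jeddah,SAU,0.007,2.847
Fremantle,Port Said,EGY,0.004,1.623
Fremantle,Barcelona,ESP,0.003,1.014
Fremantle,Gwangyang,KOR,0.002,0.814
Adelaide,Busan,KOR,0.029,11.092
Adelaide,Kaohsiung,TWN,0.024,9.246
Adelaide,Damietta,EGY,0.009,3.558
Adelaide,Keelung,TWN,0.007,2.678
Adelaide,Colombo,LKA,0.006,2.197
Adelaide,Jeddah,SAU,0.005,2.022
Adelaide,Valencia,ESP,0.005,1.919
Adelaide,Port Said,EGY,0.003,1.270
Adelaide,Barcelona,ESP,0.002,0.615
Adelaide,Algeciras,ESP,0.001,0.444
Burnie,Busan,KOR,0.0177,6.8258
Burnie,Kaohsiung,TWN,0.0149,5.7627
Burnie,Keelung,TWN,0.0049,1.8764
Burnie,Damietta,EGY,0.0026,0.9920
Burnie,Ulsan,KOR,0.0021,0.8098
Burnie,Colombo,LKA,0.0014,0.5356
Burnie,Jeddah,SAU,0.0012,0.4785
Burnie,Valencia,ESP,0.0012,0.4650
Burnie,Port Said,EGY,0.0007,0.2591
Burnie,Barcelona,ESP,0.0004,0.1726
Sydney,Busan,KOR,0.0084,3.2404
Sydney,Kaohsiung,TWN,0.0077,2.9682
Sydney,Keelung,TWN,0.0025,0.9821
Sydney,Damietta,EGY,0.0018,0.6922
Sydney,Colombo,LKA,0.0009,0.3436
Sydney,Jeddah,SAU,0.0007,0.2680
Sydney,Valencia,ESP,0.0007,0.2535
Sydney,Port Said,EGY,0.0005,0.1909
Sydney,Ulsan,KOR,0.0004,0.1463
Sydney,Barcelona,ESP,0.0003,0.1126
Hobart,Busan,KOR,0.0049,1.8767
Hobart,Kaohsiung,TWN,0.0041,1.5825
Hobart,Keelung,TWN,0.0014,0.5427
Hobart,Damietta,EGY,0.0007,0.2684
Hobart,Ulsan,KOR,0.0005,0.2113
Hobart,Colombo,LKA,0.0004,0.1521
Hobart,Jeddah,SAU,0.0004,0.1357
Hobart,Valencia,ESP,0.0004,0.1350
Hobart,Port Said,EGY,0.0002,0.0833
Hobart,Barcelona,ESP,0.0001,0.0488
Newcastle,Busan,KOR,0.00089,0.34454
Newcastle,Kaohsiung,TWN,0.00082,0.31716
Newcastle,Keelung,TWN,0.00028,0.10701
Newcastle,Damietta,EGY,0.00018,0.06883
Newcastle,Colombo,LKA,0.00009,0.03605
Newcastle,Valencia,ESP,0.00009,0.03335
Newcastle,Jeddah,SAU,0.00007,0.02564
Newcastle,Barcelona,ESP,0.00005,0.01947
Newcastle,Port Said,EGY,0.00004,0.01504
Newcastle,Karachi,PAK,0.00004,0.01407
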