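"strain","replicate","time_days","density_cells_per_ml","temperature_C"
"sim","rep1",0,10098.7,4
"sim","rep1",0.666666666666667,10047,4
"sim","rep1",1.33333333333333,9989.21,4
"sim","rep1",2,9978.74,4
"sim","rep1",2.66666666666667,10116.5,4
"sim","rep1",3.33333333333333,10130.1,4
"sim","rep1",4,10053.6,4
"sim","rep1",4.66666666666667,9987.3,4
"sim","rep1",5.33333333333333,9878.26,4
"sim","rep1",6,9888.49,4
"sim","rep2",0,9834.2,4
"sim","rep2",0.666666666666667,10047,4
"sim","rep2",1.33333333333333,10083.6,4
"sim","rep2",2,10029.3,4
"sim","rep2",2.66666666666667,9677.88,4
"sim","rep2",3.33333333333333,9985.2,4
"sim","rep2",4,9907.44,4
"sim","rep2",4.66666666666667,10045.5,4
"sim","rep2",5.33333333333333,9840.68,4
"sim","rep2",6,9800.87,4
"sim","rep1",0,10114.6,12
"sim","rep1",0.666666666666667,10031.6,12
"sim","rep1",1.33333333333333,10104.8,12
"sim","rep1",2,9978.72,12
"sim","rep1",2.66666666666667,10039.8,12
"sim","rep1",3.33333333333333,9846.82,12
"sim","rep1",4,9988.19,12
"sim","rep1",4.66666666666667,10068.7,12
"sim","rep1",5.33333333333333,9796.53,12
"sim","rep1",6,9989.06,12
"sim","rep2",0,9857.06,12
"sim","rep2",0.666666666666667,9967.52,12
"sim","rep2",1.33333333333333,9949.6,12
"sim","rep2",2,10121.1,12
"sim","rep2",2.66666666666667,9950.23,12
"sim","rep2",3.33333333333333,10039,12
"sim","rep2",4,10033.8,12
"sim","rep2",4.66666666666667,9951.19,12
"sim","rep2",5.33333333333333,9943.09,12
"sim","rep2",6,10042.9,12
"sim","rep1",0,9913.14,16
"sim","rep1",0.666666666666667,10683.3,16
"sim","rep1",1.33333333333333,13987.8,16
"sim","rep1",2,18492.6,16
"sim","rep1",2.66666666666667,23335.1,16
"sim","rep1",3.33333333333333,30794.9,16
"sim","rep1",4,40174.6,16
"sim","rep1",4.66666666666667,52470.2,16
"sim","rep1",5.33333333333333,68252.1,16
"sim","rep1",6,89927.2,16
"sim","rep2",0,9944.7,16
"sim","rep2",0.666666666666667,10602.3,16
"sim","rep2",1.33333333333333,13829,16
"sim","rep2",2,17946,16
"sim","rep2",2.66666666666667,23455.8,16
"sim","rep2",3.33333333333333,30317,16
"sim","rep2",4,40402.8,16
"sim","rep2",4.66666666666667,51996.4,16
"sim","rep2",5.33333333333333,68499.2,16
"sim","rep2",6,88170.3,16
"sim","rep1",0,10160.6,18.5
"sim","rep1",0.666666666666667,11708.1,18.5
"sim","rep1",1.33333333333333,21181.7,18.5
"sim","rep1",2,38275.4,18.5
"sim","rep1",2.66666666666667,70345.5,18.5
"sim","rep1",3.33333333333333,124843,18.5
"sim","rep1",4,220359,18.5
"sim","rep1",4.66666666666667,403907,18.5
"sim","rep1",5.33333333333333,708925,18.5
"sim","rep1",6,1186370,18.5
"sim","rep2",0,10113.8,18.5
"sim","rep2",0.666666666666667,11468.4,18.5
"sim","rep2",1.33333333333333,21130.4,18.5
"sim","rep2",2,38237.2,18.5
"sim","rep2",2.66666666666667,69333.1,18.5
"sim","rep2",3.33333333333333,124614,18.5
"sim","rep2",4,228018,18.5
"sim","rep2",4.66666666666667,403781,18.5
"sim","rep2",5.33333333333333,698158,18.5
"sim","rep2",6,1211960,18.5
"sim","rep1",0,9876.45,21
"sim","rep1",0.666666666666667,12077.8,21
"sim","rep1",1.33333333333333,24657.8,21
"sim","rep1",2,49038.2,21
"sim","rep1",2.66666666666667,101766,21
"sim","rep1",3.33333333333333,208089,21
"sim","rep1",4,411568,21
"sim","rep1",4.66666666666667,806940,21
"sim","rep1",5.33333333333333,1522720,21
"sim","rep1",6,2716080,21
"sim","rep2",0,9878.01,21
"sim","rep2",0.666666666666667,11896.4,21
"sim","rep2",1.33333333333333,24274,21
"sim","rep2",2,50250.7,21
"sim","rep2",2.66666666666667,102173,21
"sim","rep2",3.33333333333333,201584,21
"sim","rep2",4,407542,21
"sim","rep2",4.66666666666667,799518,21
"sim","rep2",5.33333333333333,1526100,21
"sim","rep2",6,2725190,21
"sim","rep1",0,10223.3,25
"sim","rep1",0.666666666666667,11097.6,25
"sim","rep1",1.33333333333333,16636.5,25
"sim","rep1",2,24557.1,25
"sim","rep1",2.66666666666667,36063.3,25
"sim","rep1",3.33333333333333,54558,25
"sim","rep1",4,80660.2,25
"sim","rep1",4.66666666666667,121415,25
"sim","rep1",5.33333333333333,176896,25
"sim","rep1",6,259950,25
"sim","rep2",0,9871.5,25
"sim","rep2",0.666666666666667,11173.8,25
"sim","rep2",1.33333333333333,16348.9,25
"sim","rep2",2,24519.2,25
"sim","rep2",2.66666666666667,36294.9,25
"sim","rep2",3.33333333333333,53368.3,25
"sim","rep2",4,82375.5,25
"sim","rep2",4.66666666666667,120659,25
"sim","rep2",5.33333333333333,177422,25
"sim","rep2",6,265320,25
"sim","rep1",0,9973.51,28.5
"sim","rep1",0.666666666666667,9967.2,28.5
"sim","rep1",1.33333333333333,9870.48,28.5
"sim","rep1",2,9980.29,28.5
"sim","rep1",2.66666666666667,9929.11,28.5
"sim","rep1",3.33333333333333,10002.9,28.5
"sim","rep1",4,9893.23,28.5
"sim","rep1",4.66666666666667,9891.42,28.5
"sim","rep1",5.33333333333333,9943.26,28.5
"sim","rep1",6,10052.1,28.5
"sim","rep2",0,9903.45,28.5
"sim","rep2",0.666666666666667,10013.4,28.5
"sim","rep2",1.33333333333333,9935.24,28.5
"sim","rep2",2,10003.7,28.5
"sim","rep2",2.66666666666667,10170.5,28.5
"sim","rep2",3.33333333333333,9916.06,28.5
"sim","rep2",4,9880.64,28.5
"sim","rep2",4.66666666666667,10052.9,28.5
"sim","rep2",5.33333333333333,10032.7,28.5
"sim","rep2",6,9970.05,28.5
"sim","rep1",0,10055.3,30
"sim","rep1",0.666666666666667,9876.13,30
"sim","rep1",1.33333333333333,9920.67,30
"sim","rep1",2,10175.9,30
"sim","rep1",2.66666666666667,10086.8,30
"sim","rep1",3.33333333333333,10073.4,30
"sim","rep1",4,10175,30
"sim","rep1",4.66666666666667,10013.8,30
"sim","rep1",5.33333333333333,10087.6,30
"sim","rep1",6,10105.6,30
"sim","rep2",0,9886.9,30
"sim","rep2",0.666666666666667,9995.64,30
"sim","rep2",1.33333333333333,10242.2,30
"sim","rep2",2,10125.2,30
"sim","rep2",2.66666666666667,9923.57,30
"sim","rep2",3.33333333333333,9709.17,30
"sim","rep2",4,10033,30
"sim","rep2",4.66666666666667,9969.47,30
"sim","rep2",5.33333333333333,9929,30
"sim","rep2",6,10029.3,30
"sim","rep1",0,10175.4,35
"sim","rep1",0.666666666666667,9999.74,35
"sim","rep1",1.33333333333333,9999.55,35
"sim","rep1",2,10157.4,35
"sim","rep1",2.66666666666667,9962.02,35
"sim","rep1",3.33333333333333,9936.91,35
"sim","rep1",4,10013.7,35
"sim","rep1",4.66666666666667,9828.95,35
"sim","rep1",5.33333333333333,10123,35
"sim","rep1",6,10222,35
"sim","rep2",0,9963.22,35
"sim","rep2",0.666666666666667,10093,35
"sim","rep2",1.33333333333333,9951.17,35
"sim","rep2",2,10020.8,35
"sim","rep2",2.66666666666667,10039.9,35
"sim","rep2",3.33333333333333,10116.3,35
"sim","rep2",4,10125,35
"sim","rep2",4.66666666666667,10016.6,35
"sim","rep2",5.33333333333333,10071.8,35
"sim","rep2",6,9962.23,35
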