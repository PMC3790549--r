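taxon,regime2,regime4,lat_north,lat_south
t01,NewGuinea,NewGuineaa,1.61376162880526,6.74792356678711
t02,Australia,Australiaa,26.4724482210002,37.8525180207214
t03,Australia,Australiaa,24.603704292828,33.1214362089873
t04,Australia,Australiaa,25.2351738203872,34.101471106391
t05,NewGuinea,NewGuineaa,4.72688869516169,10.6312943374625
t06,Australia,Australiab,22.5451338084055,30.8431995825482
t07,Australia,Australiaa,28.0234672174494,34.2256218538325
t08,Australia,Australiaa,24.4248697383989,33.9481359290619
t09,Australia,Australiab,25.4197017812287,32.0785470270669
t10,NewGuinea,NewGuineab,3.02626094552781,9.72418181183841
t11,NewGuinea,NewGuineab,-0.40361004392671,5.18719808873666
t12,NewGuinea,NewGuineaa,0.270742549402844,7.34660188372267
t13,NewGuinea,NewGuineab,-1.41626843888815,7.6854334484363
t14,Australia,Australiab,30.3924831395749,35.5358722919378
t15,Australia,Australiaa,24.9801098198742,36.5869799961448
t16,NewGuinea,NewGuineaa,1.36309868634437,12.9411331301251
t17,Australia,Australiaa,19.0125224580273,30.5840934095189
t18,NewGuinea,NewGuineab,-0.274706709502993,11.087153185786
t19,Australia,Australiaa,25.0467281755285,36.1422861036139
t20,Australia,Australiaa,26.9614780871961,37.9682451031003
t21,Australia,Australiab,28.9180468719914,36.5812767826482
t22,Australia,Australiaa,29.7867185616489,40.6054163122173
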