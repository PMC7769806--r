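year,base,resource,gini
2013,population,institutions,0.2855
2013,population,beds,0.1020
2013,population,staff,0.1080
2013,area,institutions,0.5888
2013,area,beds,0.6199
2013,area,staff,0.6751
2014,population,institutions,0.2793
2014,population,beds,0.1074
2014,population,staff,0.1090
2014,area,institutions,0.5821
2014,area,beds,0.6177
2014,area,staff,0.6738
2015,population,institutions,0.2798
2015,population,beds,0.1089
2015,population,staff,0.1080
2015,area,institutions,0.5866
2015,area,beds,0.6175
2015,area,staff,0.6710
2016,population,institutions,0.2754
2016,population,beds,0.1130
2016,population,staff,0.1028
2016,area,institutions,0.5905
2016,area,beds,0.6181
2016,area,staff,0.6661
2017,population,institutions,0.2644
2017,population,beds,0.1166
2017,population,staff,0.1024
2017,area,institutions,0.5970
2017,area,beds,0.6156
2017,area,staff,0.6671
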