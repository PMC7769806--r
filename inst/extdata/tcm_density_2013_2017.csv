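year,resource,per_1000_persons,per_1000_km2,total
2013,institutions,0.0304,0.0436,41966
2013,beds,0.5836,0.8342,794160
2013,staff,0.4403,0.6217,599114
2014,institutions,0.0319,0.0453,43635
2014,beds,0.6414,0.9104,877255
2014,staff,0.4724,0.6706,646152
2015,institutions,0.0339,0.0483,46541
2015,beds,0.6966,0.9937,957523
2015,staff,0.5055,0.7211,694827
2016,institutions,0.0358,0.0514,49527
2016,beds,0.7475,1.0726,1033547
2016,staff,0.5393,0.7739,745725
2017,institutions,0.0390,0.0563,54243
2017,beds,0.8170,1.1785,1135615
2017,staff,0.5731,0.8268,796704
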