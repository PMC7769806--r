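period,component,gt1,eq1,lt1
2013-2014,effch,13,4,14
2013-2014,techch,10,1,20
2013-2014,pech,13,9,9
2013-2014,sech,10,4,17
2013-2014,tfpch,9,0,22
2014-2015,effch,12,3,16
2014-2015,techch,4,0,27
2014-2015,pech,16,8,7
2014-2015,sech,10,3,18
2014-2015,tfpch,5,0,26
2015-2016,effch,16,4,11
2015-2016,techch,1,0,30
2015-2016,pech,8,10,13
2015-2016,sech,18,3,10
2015-2016,tfpch,4,0,27
2016-2017,effch,21,3,7
2016-2017,techch,0,0,31
2016-2017,pech,17,8,6
2016-2017,sech,20,3,8
2016-2017,tfpch,6,0,25
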