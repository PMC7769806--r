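period,effch,techch,pech,sech,tfpch
2013-2014,1.000,1.012,1.000,1.000,1.012
2014-2015,1.000,0.985,1.000,1.000,0.985
2015-2016,1.000,1.020,1.000,1.000,1.020
2016-2017,1.000,1.007,1.000,1.000,1.007
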