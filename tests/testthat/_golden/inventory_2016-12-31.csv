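# report: inventory
# as_of: 2016-12-31
breed,TOTAL,EWES,RAMS,WETHERS,LAMBS
Corriedale,5,1,1,1,2
Rambouillet,2,1,1,0,0
ALL,7,2,2,1,2
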