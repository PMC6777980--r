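# conntracer connectome; kind: count; directed: TRUE; rows = source, columns = target
region,R01,R02,R03,R04,R05,R06,R07,R08
R01,0,111,5949,728,2233,1296,0,1205
R02,97,0,299,111,76,773,3992,0
R03,6577,440,0,195,459,4696,2406,0
R04,282,284,349,0,21,2899,0,3459
R05,2035,6867,1892,801,0,336,3602,5336
R06,346,730,1169,7140,2749,0,0,0
R07,0,1568,342,0,4052,0,0,0
R08,663,0,0,1025,410,0,0,0
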