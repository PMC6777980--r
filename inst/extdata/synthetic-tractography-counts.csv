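# conntracer connectome; kind: count; directed: FALSE; rows = source, columns = target
region,R01,R02,R03,R04,R05,R06,R07,R08
R01,0,2024,471698,8049,88681,10014,106,17323
R02,2024,0,9777,1057,15016,3817,6491,100
R03,471698,9777,0,11960,85118,50109,14808,115
R04,8049,1057,11960,0,4415,60386,117,8715
R05,88681,15016,85118,4415,0,43260,65550,20979
R06,10014,3817,50109,60386,43260,0,103,118
R07,106,6491,14808,117,65550,103,0,94
R08,17323,100,115,8715,20979,118,94,0
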