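label,x,y,z
R01,5.71252866648138,14.0829448215663,13.8607040094212
R02,15.5652432562783,6.73517816700041,17.9642405547202
R03,3.55118082370609,12.749451668933,13.6863268632442
R04,3.54921312537044,5.73183154221624,2.47548192739487
R05,1.01031895261258,6.44901086576283,15.9824510430917
R06,10.5400753114372,9.65265165548772,5.13514273799956
R07,4.28642187733203,12.6278130570427,1.81771125644445
R08,1.07425095513463,9.4754239404574,18.2854282576591
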