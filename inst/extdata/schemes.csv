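scheme,category,probability
iucn50,LC,0.00005
iucn50,NT,0.004
iucn50,VU,0.05
iucn50,EN,0.42
iucn50,CR,0.97
iucn100,LC,0.0001
iucn100,NT,0.01
iucn100,VU,0.1
iucn100,EN,0.667
iucn100,CR,0.999
iucn500,LC,0.001
iucn500,NT,0.1
iucn500,VU,0.39
iucn500,EN,0.996
iucn500,CR,1
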