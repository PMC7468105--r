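class,tp,fp,fn
Asteromphalus,24,0,0
Chaetoceros,43,4,2
Fragilariopsis kerguelensis,68,2,0
Fragilariopsis rhombica,28,0,1
Nitzschia,11,0,3
Pseudonitzschia,51,1,3
Rhizosolenia,24,2,0
Silicoflagellate,37,0,0
Thalassiosira gracilis,23,0,0
Thalassiosira lentiginosa,33,0,0
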