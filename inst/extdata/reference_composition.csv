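class,n_total,n_cohort_A,n_cohort_B
Fragilariopsis kerguelensis,660,418,242
Pseudonitzschia,520,173,347
Chaetoceros,434,82,352
Silicoflagellate,342,177,165
Thalassiosira lentiginosa,311,89,222
Fragilariopsis rhombica,272,57,215
Rhizosolenia,227,153,74
Asteromphalus,223,63,160
Thalassiosira gracilis,212,88,124
Nitzschia,118,76,42
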