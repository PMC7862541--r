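host,guest,forcefield,dg_kcal,stderr_kcal
MGLab24,g2,GAFF1.81,-6.76,0.38
MGLab24,g2,CGenFF4.1,-5.25,0.11
MGLab9,g2,GAFF1.81,-3.38,0.49
MGLab9,g2,CGenFF4.1,-5.81,0.29
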