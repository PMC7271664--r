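group,scheme,f1,f2,f3,f4,f5
PD_NC,hofer,0.1,0.2,0.3,0.3,0.1
PD_NC,witelson,0.05,0.30,0.35,0.2,0.1
MSA,hofer,0,0.25,0.4,0.35,0
MSA,witelson,0,0.25,0.5,0.25,0
PSP,hofer,0,0.05,0.45,0.50,0
PSP,witelson,0,0.1,0.35,0.55,0
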