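name,Pmax,K,kmin,kmax,Kr,tau_ca,delta
depressing,0.85,0.2,0.0017,0.0517,0.1,1.5,1
muscarine,0.27,0.2,0.0017,0.0517,0.1,1.5,0.17
facilitating,0.6,4.0,0.002,6.0,0.1,30,1
mixed,0.6,1.0,0.002,6.0,0.1,30,1
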