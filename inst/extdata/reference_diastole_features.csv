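group,no,e1,e2,e3,P1,P2
cad,1,0.0015,2.8e-6,1.7e-7,0.0018,1.1e-4
cad,2,3.8e-4,1.1e-6,8.9e-8,0.0028,2.3e-4
cad,3,7.7e-4,1.9e-6,1.5e-7,0.0025,2.0e-4
cad,4,0.0015,1.9e-6,2.4e-7,0.0013,1.6e-4
cad,5,6.2e-4,1.5e-6,1.0e-7,0.0024,1.7e-4
cad,6,4.0e-4,1.1e-6,8.4e-8,0.0029,2.1e-4
normal,1,3.4e-4,2.2e-8,1.8e-10,6.4e-5,5.4e-7
normal,2,3.8e-4,3.4e-8,3.4e-10,8.8e-5,8.8e-7
normal,3,9.8e-4,1.6e-8,6.9e-11,1.6e-5,7.0e-8
normal,4,0.0014,2.1e-8,1.8e-10,1.5e-5,1.3e-7
normal,5,0.0017,1.0e-8,7.8e-11,6.0e-6,4.5e-8
normal,6,0.0013,1.6e-8,1.7e-10,1.2e-5,1.3e-7
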