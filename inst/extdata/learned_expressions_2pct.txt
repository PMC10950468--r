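# Reference distilled ventricular-interaction expressions, 2% training noise.
#target=V_spt noise=0.02
((1 / (V_ao - V_pa)) * (exp(V_rv / (V_pa - 10.05)) + 1080.36)) - 8.63
#target=P_peri noise=0.02
((1 / V_pa) * (V_rv - 91.49)) - 4.11
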