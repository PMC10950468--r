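# Reference distilled ventricular-interaction expressions, 5% training noise.
#target=V_spt noise=0.05
exp(exp(V_rv / (0.29 * (V_pa^2)))) * ((V_vc / (V_ao - V_pa)) + 2.46)
#target=P_peri noise=0.05
((1 / V_pa) * (V_rv - 88.13)) - 4.21
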