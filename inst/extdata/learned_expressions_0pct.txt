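# Reference distilled ventricular-interaction expressions, 0% training noise.
#target=V_spt noise=0
((970.58 / (V_ao - V_pa)) + (12.83 / ((V_ao - V_rv) + 2.54))) - 7.33
#target=P_peri noise=0
((V_rv * (V_rv - 105.56)) / 3227.84) - 3.72
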