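# Closed-loop six-chamber cardiovascular model: canonical constant set.
# Normal-human values of the minimal haemodynamic model (Smith et al. 2004,
# Med Eng Phys 26:131-139). Units: pressure mmHg, volume mL, time s.

# heart valve resistances (mmHg s/mL): mitral, aortic, tricuspid, pulmonary
R_mt = 0.0158
R_av = 0.018
R_tc = 0.0237
R_pv = 0.0055

# circulation resistances (mmHg s/mL)
R_sys = 1.0889
R_pul = 0.1552

# valve inertances (mmHg s^2/mL)
L_mt = 7.6968e-5
L_av = 1.2189e-4
L_tc = 8.0093e-5
L_pv = 1.4868e-4

# end-systolic elastances (mmHg/mL): ventricular free walls, septum,
# aorta, vena cava, pulmonary artery, pulmonary vein
E_lvf = 2.8798
E_rvf = 0.585
E_spt = 48.754
E_ao = 0.6913
E_vc = 0.0059
E_pa = 0.369
E_pu = 0.0073

# EDPVR constants: P(V) = P0 (exp(lambda (V - V0)) - 1)
P0_lvf = 0.1203
P0_rvf = 0.2157
P0_spt = 1.1101
P0_pcd = 0.5003
lambda_lvf = 0.033
lambda_rvf = 0.023
lambda_spt = 0.435
lambda_pcd = 0.03
V0_lvf = 0
V0_rvf = 0
V0_spt = 2
V0_pcd = 200

# dead-space (unstressed) volumes (mL)
Vd_lvf = 0
Vd_rvf = 0
Vd_spt = 2
Vd_ao = 0
Vd_vc = 0
Vd_pa = 0
Vd_pu = 0

# intrathoracic pressure (mmHg, relative to atmosphere)
P_th = -4

# Gaussian cardiac driver e(t) = A exp(-B (mod(t, period) - C)^2)
A_drv = 1
B_drv = 80
C_drv = 0.27
period = 0.75
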