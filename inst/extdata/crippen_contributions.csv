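# Atom-typed hydrophobicity (logP) and molar-refractivity contributions.
# Simplified atom typing adapted from the Ghose-Crippen / Wildman-Crippen
# atomic-contribution scheme (Wildman & Crippen, J. Chem. Inf. Comput. Sci.
# 1999, 39, 868-873): representative values per coarse type class keyed on
# element, hybridization and first-shell neighborhood rather than the full
# SMARTS typing. Hydrogen contributions are folded into the bearing heavy
# atom (type h_on_c / h_on_het per attached hydrogen).
type,logp,mr
c_sp3_plain,0.1441,2.503
c_sp3_het,-0.2035,2.753
c_sp2_plain,0.0830,3.625
c_sp2_het,-0.2783,2.350
c_carbonyl,-0.2783,1.748
c_sp,0.1334,3.243
c_ar_h,0.1581,3.350
c_ar_sub,0.1360,3.904
c_ar_het,0.0700,3.600
n_amine_prim,-1.0190,2.262
n_amine_sec,-0.7096,2.173
n_amine_tert,-0.3187,2.819
n_amide,-0.5188,2.110
n_sp2,-0.0010,2.500
n_nitrile,-0.5660,3.108
n_aromatic,-0.3239,2.202
n_charged,-4.0000,2.000
o_hydroxyl,-0.2893,0.824
o_ether,-0.0684,1.085
o_carbonyl,-0.1526,0.570
o_aromatic,0.0335,0.882
o_charged,-2.5000,0.570
s_thio,0.6482,7.110
s_aromatic,0.6237,8.005
s_oxidized,-0.0024,6.691
p_any,0.8612,6.920
f_any,0.4202,0.897
cl_any,0.6895,5.853
br_any,0.8456,8.927
i_any,0.8857,14.020
b_any,-0.3500,3.000
si_any,0.8000,7.000
h_on_c,0.1230,1.057
h_on_het,-0.2677,1.395
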