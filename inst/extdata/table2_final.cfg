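# Final population PK/PD/CO model: structural typical values.
# Units: volumes L, clearances L/h, rate constants 1/h, amounts ug,
# budesonide concentrations ng/mL, formoterol concentrations pg/mL,
# ACT in score units, time in hours.

# Budesonide PK (two-compartment, lung + gut first-order absorption)
pk.bud.Vc = 216
pk.bud.CL = 18.4
pk.bud.ka_lung = 19.7
pk.bud.ka_gut = 0.00076
pk.bud.FR = 0.38
pk.bud.Q = 88.3
pk.bud.Vp = 106

# Formoterol PK (one-compartment, lung + gut first-order absorption)
pk.fmt.Vc = 1250
pk.fmt.CL = 292
pk.fmt.ka_lung = 14.8
pk.fmt.ka_gut = 0.0524
pk.fmt.FR = 0.385

# PD: sputum ECP (inhibition of kin by lung budesonide)
pd.ecp.BASE = 19.7
pd.ecp.kout = 0.00598
pd.ecp.Imax = 1
pd.ecp.IC50 = 0.025

# PD: FEV1 (stimulation of kin by lung formoterol)
pd.fev1.BASE = 85.8
pd.fev1.kout = 0.000951
pd.fev1.Emax = 1
pd.fev1.EC50 = 0.081

# Shared lung volume for lung-concentration driver (L)
pd.V_lung = 1.1

# Clinical outcome: ACT disease-progression model
co.BASE_ACT = 19.70
co.alpha = 0.00083
co.beta1 = 0.00008
co.beta2 = 0.644

# Inter-individual variability (SD on log scale; FR on logit scale)
iiv.bud.Vc = 0.933
iiv.bud.FR = 0.06
iiv.fmt.Vc = 0.858
iiv.fmt.CL = 0.911
iiv.ecp.BASE = 1.139
iiv.ecp.kout = 0.324
iiv.fev1.BASE = 0.129
iiv.fev1.kout = 1.109
iiv.co.BASE_ACT = 0.149

# Residual variability per endpoint
rv.conc_BUD.model = proportional
rv.conc_BUD.prop = 0.642
rv.conc_FMT.model = proportional
rv.conc_FMT.prop = 0.808
rv.ECP.model = proportional
rv.ECP.prop = 0.721
rv.FEV1.model = proportional
rv.FEV1.prop = 0.0635
rv.ACT.model = additive
rv.ACT.add = 2.32
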