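name,mean,lo,hi,family,units
p_ww,0.7167,0.6878,0.8792,beta,probability
p_wm,0.2607,0.1479,0.4161,beta,probability
p_ms,0.0469,0.0178,0.1068,beta,probability
p_mm,0.0235,0.0133,0.0375,beta,probability
p_ss,0.0027,0.0010,0.0061,beta,probability
p_mw,0.9026,0.8106,0.9456,beta,probability
p_sm,0.9703,0.9598,0.9752,beta,probability
p_all_cause,0.0226,0.0186,0.0275,beta,probability
p_pneu_death,0.0270,0.0219,0.0314,beta,probability
rr_amox,0.485,0.372,0.731,lognormal,relative risk
impact,0.4338,,,fixed,proportion
dw_moderate,0.051,0.032,0.074,beta,disability weight
dw_severe,0.133,0.088,0.190,beta,disability weight
cost_per_child,0.25,0.22,0.30,gamma,USD per child
disc_cost,0.05,,,fixed,per year
disc_effect,0.05,,,fixed,per year
le_under1,54.7,,,fixed,years
le_1to4,57.9,,,fixed,years
children_u5,34600000,,,fixed,children
careseek_ppmv,0.40,,,fixed,proportion
careseek_facility,0.35,,,fixed,proportion
gdp_pc,2230,,,fixed,USD
threshold_multiplier,0.52,,,fixed,ratio
unit_inpatient_cost,39.35,,,fixed,USD per admission
n_psa,1000,,,fixed,draws
n_cycles,5,,,fixed,years
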