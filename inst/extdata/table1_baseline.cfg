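# Baseline malnutrition-model configuration (study design point)
B = 0.01
eps = 0.001
lam_b = 0.1
lam_g = 0.2
theta = 0.1
theta_b = 0.3
gam_b = 0.01
gam_g = 0.1
chi_b = 0.014
chi_g = 0.01
del_g = 0.1
theta1 = 0
theta2 = 0
sigma1 = 0.08
sigma2 = 0.09
sigma3 = 0.1
sigma4 = 0.12
Sf0 = 30
Mb0 = 2
Mg0 = 4
U0 = 1
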