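# MAP priors for the three-level mean-reverting HGF.
# value: prior mean in natural space; var: prior variance in estimation space
# (log for variance-like parameters, logit for AR(1) rates, identity
# otherwise). var: 0 fixes the parameter during inversion.
# These are the package defaults; replace this file to load a different
# prior configuration of the same structure.
parameters:
  mu3_0:    {value: -3.0, var: 4.0}   # volatility prior: the free parameter of interest
  sigma3_0: {value: 1.0,  var: 0.0}
  mu2_0:    {value: 0.0,  var: 0.0}
  sigma2_0: {value: 0.5,  var: 0.0}
  kappa:    {value: 0.2,  var: 0.0}
  omega:    {value: -0.5, var: 0.0}
  theta:    {value: 0.5,  var: 0.0}
  phi2:     {value: 0.0,  var: 0.0}
  m2:       {value: 0.0,  var: 0.0}
  phi3:     {value: 0.02, var: 0.0}
  m3:       {value: -3.0, var: 0.0}
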