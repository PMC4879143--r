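# Shared fixtures: reference parameter set and stimulus templates.
ref_params <- lumped_params()
ref_config <- model_config()

stim_1_021 <- stimulus_train(NoP = 1, PW = 0.21)
stim_1_0525 <- stimulus_train(NoP = 1, PW = 0.525)
stim_2_20 <- stimulus_train(NoP = 2, IPI = 20, PW = 0.525)
stim_2_50 <- stimulus_train(NoP = 2, IPI = 50, PW = 0.525)

# Settings that approach the fast-synapse, steep-activation limit in which
# the closed-form threshold theory is exact.
limit_params <- function(base = lumped_params())
  lumped_params(alpha1 = base$alpha1, tau1 = base$tau1, tau2 = base$tau2,
                alphaL = base$alphaL, sigmaL = base$sigmaL / 100,
                lambdaL = base$lambdaL, tauS = base$tauS / 100)
limit_config <- model_config(quad_step = 0.01)
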