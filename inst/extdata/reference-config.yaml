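# Reference configuration for the hazard model of nociceptive detection.
# Flat key-value file read by nocithresh::read_run_config().
#
# Lumped parameters (units: mA and ms; rate-like quantities in mA/ms are
# numerically identical to A/s, lambdaL in events/ms to kHz):
alpha1: 0.125      # activation threshold of afferent fibers, mA
tau1: 0.2          # afferent membrane time constant, ms
tau2: 45           # secondary-neuron membrane time constant, ms
alphaL: 0.00417    # central activation threshold, mA/ms
sigmaL: 8.33e-5    # central slope parameter, mA/ms
lambdaL: 0.01      # maximal population firing rate, events/ms
tauS: 1.5          # synaptic time constant, ms
#
# Numerical settings:
window_factor: 15  # trial window = last pulse + window_factor * tau2
quad_tol: 1.0e-9   # target absolute error of the expected spike count
root_tol: 1.0e-6   # absolute tolerance on A50, mA
amplitude_bracket_max: 1000  # mA; bracket expansion limit
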