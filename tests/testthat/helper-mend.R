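# Shared fixtures; everything is generated in code.

fp_default <- fixed_params()

test_soil <- function(seed = 1) generate_soil(seed = seed)

# A fast, well-behaved parameter set for simulation tests
mp_ref <- microbial_defaults()

random_state <- function() {
  pool_state(P1 = runif(1, 0, 10), P2 = runif(1, 0, 10), M = runif(1, 0, 40),
             D = runif(1, 0, 0.5), Q = runif(1, 0, 1), BA = runif(1, 0, 0.5),
             BD = runif(1, 0, 1), EP1 = runif(1, 0, 0.01),
             EP2 = runif(1, 0, 0.01), EM = runif(1, 0, 0.01),
             CO2 = runif(1, 0, 5))
}

random_mp <- function() {
  microbial_params(r0 = runif(1, 0.05, 1), Vg = runif(1, 0.005, 0.15),
                   alpha = runif(1, 0.05, 0.55), KD = runif(1, 0.001, 0.4),
                   Yg = runif(1, 0.15, 0.65))
}

random_env <- function() {
  mend_env(T = runif(1, 5, 35), IP1 = runif(1, 0, 1e-4),
           IP2 = runif(1, 0, 1e-4), ID = runif(1, 0, 1e-4))
}
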