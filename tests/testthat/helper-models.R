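# Shared fixtures, all built in code.

plateau_r10 <- plateau_profile("reproduction", 10)
plateau_a5 <- plateau_profile("mortality", 5)

# Plateau-habitat Beverton-Holt model used throughout (the baseline study
# configuration: m = 5, l = 10, tau = 1).
baseline_model <- function(q = 1, D = 1, tau = 1,
                           kernel = kernel_spec(sd = 2)) {
  model_spec(D = D, q = q, tau = tau,
             reaction = reaction_spec("logistic_mortality",
                                      alpha_profile = plateau_a5),
             birth = birth_spec("beverton_holt", r_profile = plateau_r10),
             kernel = kernel)
}

# Spatially homogeneous surrogate with constant coefficients.
homogeneous_model <- function(alpha0 = 0, r0 = 2, q = 0,
                              kernel = kernel_spec(sd = 2)) {
  model_spec(q = q,
             reaction = reaction_spec("logistic_mortality",
                                      alpha_profile = constant_profile(alpha0)),
             birth = birth_spec("beverton_holt",
                                r_profile = constant_profile(r0)),
             kernel = kernel)
}

small_grid <- function() spatial_grid(60, 1201)   # spacing 0.1

# Seeded ordered pairs / smooth fields for property tests (fixture grid has
# spacing 0.2, so season solves on it use dt = tau/16).
fixtures_42 <- generate_fixtures(42)
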