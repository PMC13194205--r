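test_that("plateau profiles reproduce the printed piecewise branches", {
  r <- plateau_profile("reproduction", 10)
  a <- plateau_profile("mortality", 5)
  expect_equal(profile_eval(r, 0), 2)
  expect_equal(profile_eval(a, 12), 1)
  expect_equal(profile_eval(r, 15), 1.5)
  expect_equal(profile_eval(r, -15), 1.5)
  expect_equal(profile_eval(r, c(-25, 25)), c(1, 1))   # constant tails
  expect_equal(profile_eval(a, c(-4, 0, 4)), c(0, 0, 0))
  expect_equal(profile_eval(a, 7.5), 0.5)
  expect_error(plateau_profile("reproduction", -1), "positive")
})

test_that("plateau profiles are continuous at the ramp breakpoints", {
  for (p in list(plateau_profile("reproduction", 10),
                 plateau_profile("mortality", 5))) {
    brk <- p$scale * c(-2, -1, 1, 2)
    eps <- 1e-9
    jump <- abs(profile_eval(p, brk + eps) - profile_eval(p, brk - eps))
    expect_lt(max(jump), 1e-6)
  }
})

test_that("periodic profiles match the printed branches with a continuous ascent", {
  r1 <- periodic_profile("reproduction", 15)
  expect_equal(profile_eval(r1, 0), 2)
  expect_equal(profile_eval(r1, 40), 1)
  # ascending branch: the continuity-consistent ramp x/l - 2
  expect_equal(profile_eval(r1, 52.5), 1.5)
  # branch endpoints join continuously
  eps <- 1e-9
  brk <- 15 * c(1, 2, 3, 4) + 5 * 15 * c(-1, 0, 1)[rep(1:3, each = 4)]
  jump <- abs(profile_eval(r1, brk + eps) - profile_eval(r1, brk - eps))
  expect_lt(max(jump), 1e-6)

  a1 <- periodic_profile("mortality", 10)
  expect_equal(profile_eval(a1, 0), 0)
  expect_equal(profile_eval(a1, 25), 1)
  expect_equal(profile_eval(a1, 35), 0.5)   # corrected descending ramp
})

test_that("periodic profiles have period 5*scale and stay in range", {
  for (p in list(periodic_profile("reproduction", 15),
                 periodic_profile("mortality", 10))) {
    x <- seq(-400, 400, length.out = 1000)
    expect_lt(max(abs(profile_eval(p, x + 5 * p$scale) - profile_eval(p, x))),
              1e-12)
    v <- profile_eval(p, x)
    expect_gte(min(v), min(p$levels))
    expect_lte(max(v), max(p$levels))
  }
})

test_that("model validators accept the study families and catch violations", {
  expect_true(validate_model(baseline_model()))
  m6 <- model_spec(q = 1,
                   reaction = reaction_spec("logistic_mortality",
                                            alpha_profile = plateau_a5),
                   birth = birth_spec("logistic_nonmonotone",
                                      r_profile = plateau_r10),
                   kernel = kernel_spec(sd = 2))
  expect_true(validate_model(m6))
  bad <- model_spec(q = 0,
                    reaction = reaction_spec("custom",
                                             f = function(x, u) 1 + 0 * u,
                                             theta = function(x) 0 * x,
                                             bound_K = 1),
                    birth = birth_spec("linear", eta0 = 1),
                    kernel = kernel_spec(sd = 2))
  expect_error(validate_model(bad), "f\\(x, 0\\)")
})

test_that("the bounded-favourable-habitat check uses the tail limits", {
  # plateau baseline: eta tail 1, theta tail -1, tau 1 -> exp(-1), holds
  rep1 <- check_assumption_A(baseline_model())
  expect_true(rep1$holds)
  expect_equal(rep1$lhs, exp(-1))
  # constant eta 2, theta 0 -> 2, fails
  m2 <- model_spec(q = 0,
                   reaction = reaction_spec("linear", theta0 = 0),
                   birth = birth_spec("linear", eta0 = 2),
                   kernel = kernel_spec(sd = 2))
  rep2 <- check_assumption_A(m2)
  expect_false(rep2$holds)
  expect_equal(rep2$lhs, 2)
  # eta tail 0.5, theta tail 0 -> 0.5, holds
  m3 <- model_spec(q = 0,
                   reaction = reaction_spec("linear", theta0 = 0),
                   birth = birth_spec("linear", eta0 = 0.5),
                   kernel = kernel_spec(sd = 2))
  expect_true(check_assumption_A(m3)$holds)
})

test_that("the habitat check holds for plateau-tailed scenarios and fails for fully periodic ones", {
  held <- c(
    fig1 = check_assumption_A(build_scenario("fig1", q = 1)$model)$holds,
    fig2 = check_assumption_A(build_scenario("fig2", q = 1, mu = 0)$model)$holds,
    fig3 = check_assumption_A(build_scenario("fig3", q = 1, sigma = 2)$model)$holds,
    fig4 = check_assumption_A(build_scenario("fig4", m = 10)$model)$holds,
    fig6 = check_assumption_A(build_scenario("fig6", q = 1, sigma = 2)$model)$holds)
  expect_true(all(held))
  # periodic mortality: favourable patches recur at infinity, limsup theta = 0
  rep5 <- check_assumption_A(build_scenario("fig5", m = 10)$model)
  expect_false(rep5$holds)
  expect_equal(rep5$lhs, 2)
})

test_that("the invariance bound follows the two-branch formula", {
  expect_equal(invariance_bound(K = 2, M = 4, Ntilde = 7), 2)
  expect_equal(invariance_bound(K = -1, M = 3, Ntilde = 1), 3)
  expect_equal(invariance_bound(K = 0, M = 2, Ntilde = 0), 1)
  expect_error(invariance_bound(K = -2, M = 1, Ntilde = 1), "K \\+ M")
})

test_that("the L*exp(K*tau) compatibility check warns instead of blocking", {
  # the standard simulation constants violate the bound
  expect_warning(rep1 <- check_LK_condition(baseline_model()), "> 1")
  expect_equal(rep1$value, 2)
  expect_false(rep1$holds)

  m2 <- model_spec(q = 0,
                   reaction = reaction_spec("logistic_mortality",
                                            alpha_profile = plateau_a5,
                                            bound_K = -1),
                   birth = birth_spec("beverton_holt", r_profile = plateau_r10),
                   kernel = kernel_spec(sd = 2))
  expect_warning(rep2 <- check_LK_condition(m2), NA)
  expect_equal(rep2$value, 2 * exp(-1))
  expect_true(rep2$holds)

  m3 <- model_spec(q = 0, tau = 5,
                   reaction = reaction_spec("linear", theta0 = 0, bound_K = 0),
                   birth = birth_spec("linear", eta0 = 1),
                   kernel = kernel_spec(sd = 2))
  rep3 <- check_LK_condition(m3)
  expect_equal(rep3$value, 1)
  expect_true(rep3$holds)   # boundary case
})
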