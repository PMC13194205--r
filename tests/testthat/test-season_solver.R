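test_that("advected heat-kernel propagation matches Gaussian closed forms", {
  g <- spatial_grid(40, 1601)   # spacing 0.05
  # constants are invariant under pure transport (interior)
  u <- density_field(g, 3)
  out <- greens_propagate(u, D = 1, q = 0, t = 1)
  margin <- 8 * sqrt(2) + g$spacing   # full sampled-kernel footprint
  interior <- abs(g$nodes) < g$half_width - margin
  expect_lt(max(abs(out$values[interior] - 3)), 1e-10)
  # t = 0 is the identity
  expect_identical(greens_propagate(u, 1, 0, 0)$values, u$values)
  # a point mass drifts to x = q t
  pm <- density_field(g, as.numeric(abs(g$nodes) < g$spacing / 2) / g$spacing)
  drifted <- greens_propagate(pm, D = 1, q = 2, t = 1)
  expect_lt(abs(g$nodes[which.max(drifted$values)] - 2), g$spacing + 1e-12)
  # Gaussian in, Gaussian out with variances added
  s0 <- 2
  phi <- density_field(g, exp(-g$nodes^2 / (2 * s0^2)))
  out2 <- greens_propagate(phi, D = 1, q = 0, t = 1)
  ssq <- s0^2 + 2
  exact <- s0 / sqrt(ssq) * exp(-g$nodes^2 / (2 * ssq))
  expect_lt(max(abs(out2$values - exact)), 1e-10)
  expect_error(greens_propagate(phi, 1, 0, -1), "nonnegative")
})

test_that("the Bernoulli reaction step is exact", {
  expect_equal(reaction_step_exact(1, 0, 1), 0.5)
  expect_equal(reaction_step_exact(1, 1, 0), 1)
  expect_equal(reaction_step_exact(1, 1, 1), exp(-1) / (2 - exp(-1)))
  # independent oracle: stiff ODE integration of du/dt = -alpha u - u^2
  ode_oracle <- function(u0, alpha, t) {
    out <- deSolve::lsoda(y = c(u = u0), times = c(0, t),
                          func = function(t, y, p) list(-alpha * y - y^2),
                          rtol = 1e-12, atol = 1e-14)
    out[2, "u"]
  }
  for (case in list(c(1, 1, 1), c(2, 0.3, 0.7), c(0.2, 0, 2.5))) {
    expect_equal(reaction_step_exact(case[1], case[2], case[3]),
                 unname(ode_oracle(case[1], case[2], case[3])),
                 tolerance = 1e-9)
  }
  # semigroup property: two half steps equal one full step
  half <- reaction_step_exact(reaction_step_exact(1.3, 0.8, 0.5), 0.8, 0.5)
  expect_equal(half, reaction_step_exact(1.3, 0.8, 1), tolerance = 1e-14)
  expect_error(reaction_step_exact(-1, 0, 1), "nonnegative")
})

test_that("the season solver agrees with closed-form references", {
  g <- small_grid()
  mc <- homogeneous_model(alpha0 = 0.5)
  # zero stays zero
  z <- solve_season(mc, density_field(g, 0))
  expect_equal(field_sup(season_final(z)), 0)
  # constant initial + uniform mortality: interior values follow the
  # Bernoulli closed form (transport leaves constants invariant)
  sol <- solve_season(mc, density_field(g, 1))
  interior <- abs(g$nodes) < 30
  expect_lt(max(abs(season_final(sol)$values[interior] -
                    reaction_step_exact(1, 0.5, 1))), 1e-6)
  # linear reaction family: full solution equals the advected heat kernel
  # with an exponential tilt
  ml <- model_spec(q = 1, reaction = reaction_spec("linear", theta0 = -0.5),
                   birth = birth_spec("linear", eta0 = 1),
                   kernel = kernel_spec(sd = 2))
  g2 <- spatial_grid(40, 2049)
  phi <- density_field(g2, exp(-g2$nodes^2 / 8))
  num <- season_final(solve_season(ml, phi, dt = 1 / 64))
  oracle <- greens_propagate(phi, D = 1, q = 1, t = 1, mu_shift = 0.5)
  expect_lt(max(abs(num$values - oracle$values)) / max(oracle$values), 1e-3)
  expect_error(solve_season(ml, phi, dt = 0.3), "divide")
})

test_that("pure transport conserves mass away from the boundary", {
  g <- spatial_grid(60, 1201)
  m0 <- model_spec(q = 0, reaction = reaction_spec("linear", theta0 = 0),
                   birth = birth_spec("linear", eta0 = 1),
                   kernel = kernel_spec(sd = 2))
  phi <- density_field(g, exp(-g$nodes^2 / 18))   # support well inside
  sol <- solve_season(m0, phi, dt = 1 / 32)
  expect_lt(abs(field_mass(season_final(sol)) - field_mass(phi)) /
            field_mass(phi), 1e-6)
})

test_that("the season semiflow preserves the ordering of initial data", {
  model <- baseline_model(q = 1)
  for (pair in fixtures_42$pairs) {
    a <- season_final(solve_season(model, pair$phi, dt = 1 / 16))
    b <- season_final(solve_season(model, pair$psi, dt = 1 / 16))
    expect_lt(max(a$values - b$values), 1e-8)
  }
})

test_that("the splitting converges at second order in the substep", {
  g <- spatial_grid(20, 1001)   # spacing 0.04
  # smooth spatially varying coefficient (ramp kinks would mask the clean
  # splitting order with a lower-order local error)
  lf <- linear_field(function(x) -exp(-x^2 / 50), D = 1, q = 1)
  phi <- density_field(g, exp(-g$nodes^2 / 8))
  ref <- linear_propagate(lf, phi, t = 1, dt = 1 / 256)
  errs <- vapply(c(16, 32, 64), function(k) {
    max(abs(linear_propagate(lf, phi, t = 1, dt = 1 / k)$values - ref$values))
  }, numeric(1))
  order <- stats::coef(stats::lm.fit(cbind(1, log(c(16, 32, 64))),
                                     log(errs)))[2]
  expect_lt(order, -1.8)   # error ~ dt^p with p >= 1.8
})

test_that("linear propagation is linear, positive and exact for constants", {
  g <- small_grid()
  interior <- abs(g$nodes) < 30
  lf0 <- linear_field(0, D = 1, q = 0)
  c0 <- linear_propagate(lf0, density_field(g, 2), t = 1, dt = 1 / 16)
  expect_lt(max(abs(c0$values[interior] - 2)), 1e-10)
  lfc <- linear_field(-0.7, D = 1, q = 0)
  ce <- linear_propagate(lfc, density_field(g, 2), t = 1, dt = 1 / 16)
  expect_lt(max(abs(ce$values[interior] - 2 * exp(-0.7))), 1e-9)
  # plateau coefficient: squeezed between constant-coefficient envelopes
  lfa <- linear_field(function(x) -plateau_profile("mortality", 5)$fun(x),
                      D = 1, q = 0)
  mid <- linear_propagate(lfa, density_field(g, 1), t = 1, dt = 1 / 32)
  expect_true(all(mid$values[interior] <= 1 + 1e-9))
  expect_true(all(mid$values[interior] >= exp(-1) - 1e-9))
  expect_true(all(mid$values >= 0))
})
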