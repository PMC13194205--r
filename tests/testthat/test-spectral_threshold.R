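test_that("the tent cutoff matches its formula", {
  expect_equal(zeta_cutoff(3, 0), 1)
  expect_equal(zeta_cutoff(3, 2.5), 0.5)
  expect_equal(zeta_cutoff(3, 4), 0)
  expect_equal(zeta_cutoff(3, -2.5), 0.5)
  expect_true(all(zeta_cutoff(5, seq(-10, 10, 0.1)) >= 0))
  expect_true(all(zeta_cutoff(5, seq(-10, 10, 0.1)) <= 1))
  expect_error(zeta_cutoff(-1, 0), "positive")
})

spec_grid <- spatial_grid(80, 801)   # spacing 0.2

test_that("the assembled operator has the factored structure it claims", {
  k <- kernel_spec(sd = 2)
  # eta = 0 kills the operator
  lin0 <- linearize(eta0 = 0, theta0 = 0, q = 0, kernel = k)
  M0 <- assemble_operator(lin0, spec_grid, dt = 1 / 16)
  expect_equal(max(abs(M0$entries)), 0)
  # homogeneous eta0: interior row sums x spacing recover eta0
  lin2 <- linearize(eta0 = 2, theta0 = 0, q = 0, kernel = k)
  M2 <- assemble_operator(lin2, spec_grid, dt = 1 / 16)
  ones <- rep(1, spec_grid$n_nodes)
  action <- as.numeric(M2$entries %*% ones)
  interior <- abs(spec_grid$nodes) < 40
  expect_lt(max(abs(action[interior] - 2)), 1e-8)
  # entries of a positive operator are nonnegative
  expect_gte(min(M2$entries), 0)
})

test_that("matrix action agrees with the composed application", {
  k <- kernel_spec(sd = 2)
  g <- fixtures_42$grid
  lin <- linearize(baseline_model(q = 1))
  M <- assemble_operator(lin, g, dt = 1 / 16)
  lf <- linear_field(lin$theta, D = 1, q = 1)
  kplan <- impulseRAD:::kernel_conv_plan(discretize_kernel(k, g))
  eta_vals <- lin$eta(g$nodes)
  for (f in fixtures_42$fields) {
    composed <- impulseRAD:::conv_apply(
      kplan,
      eta_vals * linear_propagate(lf, f, t = 1, dt = 1 / 16)$values)
    direct <- as.numeric(M$entries %*% f$values)
    expect_lt(max(abs(direct - composed)), 1e-10)
  }
})

test_that("the assembled operator is linear and positive in its argument", {
  lin <- linearize(baseline_model(q = 1))
  g <- fixtures_42$grid
  M <- assemble_operator(lin, g, dt = 1 / 16)
  phi <- fixtures_42$fields[[1]]$values
  psi <- fixtures_42$fields[[2]]$values
  lhs <- as.numeric(M$entries %*% (2.5 * phi - 0.5 * psi))
  rhs <- 2.5 * as.numeric(M$entries %*% phi) -
    0.5 * as.numeric(M$entries %*% psi)
  expect_lt(max(abs(lhs - rhs)), 1e-10)
  expect_gte(min(M$entries %*% phi), -1e-12)
})

test_that("truncation scales columns by the cutoff and is dominated", {
  lin <- linearize(eta0 = 2, theta0 = 0, q = 0, kernel = kernel_spec(sd = 2))
  M <- assemble_operator(lin, spec_grid, dt = 1 / 16)
  Mt <- truncated_operator(M, 40)
  expect_lte(spectral_radius(Mt), spectral_radius(M) + 1e-10)
  expect_error(truncated_operator(M, 100), "half-width")
  # tiny radius: every cutoff weight below one
  Ms <- truncated_operator(M, 0.5)
  expect_true(all(zeta_cutoff(0.5, Ms$nodes) < 1))
})

test_that("spectral radius methods agree and match analytic cases", {
  expect_equal(spectral_radius(diag(c(0.2, 0.7, 0.3))), 0.7)
  a <- c(1, 2, 3); b <- c(0.4, 0.1, 0.2)
  expect_equal(spectral_radius(outer(a, b), method = "power"), sum(a * b),
               tolerance = 1e-9)
  lin <- linearize(eta0 = 2, theta0 = 0, q = 0, kernel = kernel_spec(sd = 2))
  Mt <- truncated_operator(assemble_operator(lin, spec_grid, dt = 1 / 16), 60)
  r_dense <- spectral_radius(Mt, method = "dense_eig")
  r_power <- spectral_radius(Mt, method = "power")
  expect_lt(abs(r_dense - r_power) / r_dense, 1e-6)
  expect_gt(r_dense, 0)
  expect_lt(r_dense, 2)
})

test_that("the spectral sweep recovers homogeneous closed forms and is monotone", {
  g <- spatial_grid(100, 1001)
  k <- kernel_spec(sd = 2)
  cases <- list(list(eta0 = 2, theta0 = 0),
                list(eta0 = 1, theta0 = -1))
  for (cs in cases) {
    lin <- linearize(eta0 = cs$eta0, theta0 = cs$theta0, q = 0, tau = 1,
                     kernel = k)
    sw <- suppressWarnings(estimate_rho_L(lin, g))
    target <- cs$eta0 * exp(cs$theta0)
    expect_lt(abs(sw$rho_L_estimate - target) / target, 0.02)
    expect_true(all(diff(sw$rho_values) > -1e-10))
  }
  # eta = 0: zero at every radius
  lin0 <- linearize(eta0 = 0, theta0 = 0, q = 0, kernel = k)
  sw0 <- estimate_rho_L(lin0, g)
  expect_equal(max(abs(sw0$rho_values)), 0)
  expect_error(estimate_rho_L(lin0, g, radii = c(10, 20)), "3")
})

test_that("the linearisation approximates the full map to second order at low density", {
  g <- small_grid()
  model <- baseline_model(q = 1)
  lin <- linearize(model)
  M <- assemble_operator(lin, g, dt = 1 / 32)
  phi <- exp(-g$nodes^2 / 32)   # smooth, well inside the domain
  Lphi <- as.numeric(M$entries %*% phi)
  eps <- c(1e-2, 1e-3, 1e-4)
  resid <- vapply(eps, function(e) {
    Qe <- generation_step(model, density_field(g, e * phi), dt = 1 / 32)
    max(abs(Qe$values - e * Lphi))
  }, numeric(1))
  order <- stats::coef(stats::lm.fit(cbind(1, log(eps)), log(resid)))[2]
  expect_gt(order, 1.8)
})
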