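test_that("transition density is the drifted Gaussian and integrates to one", {
  ev <- evidence(0, 1, 1)
  expect_equal(transition_density(0, 1, 0, 0, ev), 1 / sqrt(2 * pi),
               tolerance = 1e-12)
  # reflection symmetry at zero drift
  x <- seq(-2, 2, by = 0.25)
  expect_equal(transition_density(x, 1.3, 0.4, 0.1, ev),
               transition_density(2 * 0.4 - x, 1.3, 0.4, 0.1, ev))
  # quadrature oracle: density integrates to 1 on a wide grid
  ev2 <- evidence(0.05, 0.1, 0.01)
  for (dt in c(0.1, 1)) {
    g <- seq(-6, 6 + ev2$xi * dt, by = 0.001)
    expect_equal(trapz(g, transition_density(g, dt, 0, 0, ev2)), 1,
                 tolerance = 1e-6)
  }
  expect_error(transition_density(0, 1, 0, 2, ev), "greater")
  # CDF is the matching Gaussian probability
  expect_equal(transition_cdf(0.5, 1, 0, 0, ev), pnorm(0.5))
})

test_that("psi kernel vanishes on the chord and reduces for constant boundaries", {
  ev <- evidence(0.01, 0.1, 0.01)
  t <- 0.5; tau <- 0.2; a <- 0.8
  # y on the chord: a' = (a - y)/(t - tau) makes the bracket vanish
  a_deriv <- -0.7
  y <- a - a_deriv * (t - tau)
  expect_equal(psi_kernel(a, a_deriv, t, y, tau, ev), 0)
  # constant boundary: Psi = -f (a - y)/(2 (t - tau))
  y2 <- 0.1
  f <- transition_density(a, t, y2, tau, ev)
  expect_equal(psi_kernel(a, 0, t, y2, tau, ev),
               -f * (a - y2) / (2 * (t - tau)))
  expect_error(psi_kernel(a, 0, 0.2, 0, 0.5, ev), "greater")
})

test_that("psi kernel stays bounded approaching the diagonal on a smooth boundary", {
  ev <- evidence(0, 0.1, 0.01)
  a_fun <- function(t) exp(-t)
  t <- 0.5
  gaps <- 10^seq(-2, -8, by = -1)
  vals <- vapply(gaps, function(h) {
    psi_kernel(a_fun(t), -exp(-t), t, a_fun(t - h), t - h, ev)
  }, numeric(1))
  expect_true(all(is.finite(vals)))
  # magnitude shrinks as the gap closes (the limit is 0)
  expect_true(abs(vals[[length(vals)]]) < abs(vals[[1]]))
  expect_lt(abs(vals[[length(vals)]]), 1e-2)
})

test_that("solver matches the analytic constant-boundary series", {
  for (mu in c(0, 0.05)) {
    ev <- evidence(mu, 0.1, 0.01)
    n <- 900
    d <- solve_fpt(boundary_constant(1, n, 0.01), ev)
    a <- analytic_fpt_constant(1, ev, n)
    g <- attr(d, "g"); ga <- attr(a, "g")
    expect_lt(max(abs(g$g_upper - ga$g_upper), abs(g$g_lower - ga$g_lower)),
              1e-3)
    expect_equal(choice_prob(d), attr(a, "p_upper_exact"), tolerance = 1e-4)
  }
})

test_that("zero drift with symmetric boundaries gives a symmetric solution", {
  ev <- evidence(0, 0.1, 0.01)
  d <- solve_fpt(boundary_constant(1, 600, 0.01), ev)
  expect_equal(choice_prob(d), 0.5, tolerance = 1e-10)
  expect_equal(d$p_upper, d$p_lower, tolerance = 1e-12)
})

test_that("solution satisfies the first-kind renewal relation", {
  ev <- evidence(0.01, 0.1, 0.01)
  b <- bounds_exp(n_steps = 250)
  d <- solve_fpt(b, ev)
  expect_lt(first_kind_residual(b, ev, d), 0.02)
})

test_that("solver conserves probability across parameter regimes", {
  for (mu in c(0, 0.01, 0.05)) {
    for (sigma in c(0.1, 0.12)) {
      ev <- evidence(mu, sigma, 0.01)
      d <- solve_fpt(boundary_constant(1, 1500, 0.01), ev)
      expect_gte(total_mass(d), 0.999)
      expect_lte(total_mass(d), 1 + 1e-2)
    }
  }
})

test_that("scaling sigma, boundaries and start by c leaves the outcome unchanged", {
  ev1 <- evidence(0, 0.1, 0.01)
  ev2 <- evidence(0, 0.25, 0.01)
  c_fac <- 2.5
  b1 <- bounds_exp(a0 = 1, n_steps = 250)
  b2 <- bounds_exp(a0 = c_fac, n_steps = 250)
  d1 <- solve_fpt(b1, ev1)
  d2 <- solve_fpt(b2, ev2)
  expect_equal(d1$p_upper, d2$p_upper, tolerance = 1e-10)
  expect_equal(d1$p_lower, d2$p_lower, tolerance = 1e-10)
})

test_that("negating drift and mirroring boundaries swaps the two outcomes", {
  ev_pos <- evidence(0.03, 0.1, 0.01)
  ev_neg <- evidence(-0.03, 0.1, 0.01)
  n <- 250
  b <- boundary_from_fun(function(t) exp(-0.5 * t),
                         function(t) -exp(-1.5 * t), n, 0.01)
  b_mirror <- boundary_from_fun(function(t) exp(-1.5 * t),
                                function(t) -exp(-0.5 * t), n, 0.01)
  d <- solve_fpt(b, ev_pos)
  dm <- solve_fpt(b_mirror, ev_neg)
  expect_equal(d$p_upper, dm$p_lower, tolerance = 1e-12)
  expect_equal(d$p_lower, dm$p_upper, tolerance = 1e-12)
})

test_that("per-time-unit densities converge as the step is refined", {
  # reference: a much finer grid; discrepancy at shared times must decrease
  # monotonically across step = 0.02, 0.01, 0.005
  a_fun <- function(t) exp(-t)
  ref_step <- 0.00125
  ev_ref <- evidence(0.01 * ref_step / 0.01, 0.1 * sqrt(ref_step / 0.01),
                     ref_step)  # same xi and s2 as the coarser grids
  n_ref <- round(2 / ref_step)
  d_ref <- solve_fpt(boundary_from_fun(a_fun, function(t) -a_fun(t),
                                       n_ref, ref_step), ev_ref)
  g_ref <- attr(d_ref, "g")$g_upper
  errs <- vapply(c(0.02, 0.01, 0.005), function(st) {
    ev <- evidence(0.01 * st / 0.01, 0.1 * sqrt(st / 0.01), st)  # same xi, s2
    n <- round(2 / st)
    d <- solve_fpt(boundary_from_fun(a_fun, function(t) -a_fun(t), n, st), ev)
    idx_ref <- round((seq_len(n) * st) / ref_step)
    max(abs(attr(d, "g")$g_upper - g_ref[idx_ref]))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("touching boundaries truncate with a warning and absorb the rest", {
  ev <- evidence(0, 0.1, 0.01)
  b <- boundary_from_fun(function(t) 0.3 - 0.4 * t, function(t) -0.3 + 0.4 * t,
                         120, 0.01)
  expect_warning(d <- solve_fpt(b, ev), "touch")
  expect_gte(total_mass(d), 0.999)
  expect_lte(total_mass(d), 1 + 1e-2)  # forced absorption up to quadrature error
})

test_that("solver rejects inconsistent inputs", {
  ev <- evidence(0, 0.1, 0.02)
  expect_error(solve_fpt(boundary_constant(1, 10, 0.01), ev), "same step")
  ev2 <- evidence(0, 0.1, 0.01)
  expect_error(solve_fpt(boundary_constant(1, 10, 0.01), ev2,
                         state = diffusion_state(x0 = 2)), "between")
})
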