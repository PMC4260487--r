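test_that("constant boundaries are recovered exactly from the analytic law", {
  ev <- evidence(0.01, 0.1, 0.01)
  target <- analytic_fpt_constant(1, ev, 900)
  fit <- invert_boundaries(target, ev, inversion_config())
  reg <- mass_region(fit$target)
  expect_lt(max(abs(fit$bounds$upper[reg] - 1)), 0.01)   # one grid cell
  expect_lt(max(abs(fit$bounds$lower[reg] + 1)), 0.01)
  expect_lt(fit$tv, 0.01)
})

test_that("inversion is deterministic given target and config", {
  ev <- ev_std()
  target <- solve_fpt(bounds_exp(n_steps = 150), ev)
  f1 <- invert_boundaries(target, ev, inversion_config())
  f2 <- invert_boundaries(target, ev, inversion_config())
  expect_identical(f1$bounds$upper, f2$bounds$upper)
  expect_identical(f1$bounds$lower, f2$bounds$lower)
  expect_identical(f1$main_until, f2$main_until)
})

test_that("truncated targets are renormalized before inversion", {
  ev <- evidence(0.01, 0.1, 0.01)
  full <- analytic_fpt_constant(1, ev, 900)
  cut <- fpt_dist(full$p_upper[1:400], full$p_lower[1:400], 0.01)
  expect_lt(total_mass(cut), 0.999)
  fit <- invert_boundaries(cut, ev, inversion_config())
  expect_equal(total_mass(fit$target), 1, tolerance = 1e-12)
})

test_that("collapsing boundaries are recovered essentially exactly", {
  ev <- ev_std()
  truth <- bounds_exp(n_steps = 300)
  target <- solve_fpt(truth, ev)
  fit <- piecewise_refine(invert_boundaries(target, ev, inversion_config()))
  err_u <- abs(fit$bounds$upper - truth$upper)
  err_l <- abs(fit$bounds$lower - truth$lower)
  reg <- mass_region(fit$target)
  # sub-grid (root-polished) recovery across the whole mass-bearing region;
  # beyond it the recursion eventually loses the boundary to its intrinsic
  # instability, which the critical-step detector flags
  expect_lt(max(err_u[reg], err_l[reg]), 1e-6)
  expect_lt(fit$tv, 0.01)
  expect_gte(fit$main_until, max(reg))
})

test_that("refinement is a no-op when every step already meets tolerance", {
  ev <- evidence(0.01, 0.1, 0.01)
  target <- analytic_fpt_constant(1, ev, 700)
  fit <- invert_boundaries(target, ev, inversion_config())
  expect_equal(fit$main_until, nrow(fit$bounds))
  refined <- piecewise_refine(fit)
  expect_identical(refined$bounds$upper, fit$bounds$upper)
  expect_identical(refined$bounds$lower, fit$bounds$lower)
})

test_that("refinement never increases the total tail objective", {
  target <- accumulator_fpt(acc_spec(0.05, 0.1), 300)
  ev <- evidence(0.05, 0.1, 0.01)
  fit <- invert_boundaries(target, ev, inversion_config())
  refined <- piecewise_refine(fit)
  expect_lte(refined$objective, fit$objective + 1e-12)
  expect_lt(refined$tv, fit$tv)
})

test_that("accumulator targets yield collapsing, asymmetric boundaries", {
  target <- accumulator_fpt(acc_spec(0.05, 0.1), 300)
  ev <- evidence(0.05, 0.1, 0.01)
  fit <- piecewise_refine(invert_boundaries(target, ev, inversion_config()))
  b <- fit$bounds
  reg <- mass_region(fit$target, 0.05, 0.95)
  # both converge toward zero across the mass region
  expect_lt(b$upper[[max(reg)]], 0.5 * b$upper[[min(reg)]])
  expect_gt(b$lower[[max(reg)]], 0.5 * b$lower[[min(reg)]])
  # the lower boundary approaches zero sooner than the upper
  first_near0 <- function(x) {
    i <- which(abs(x) <= 0.05)
    if (length(i)) i[[1]] else Inf
  }
  expect_lt(first_near0(b$lower), first_near0(b$upper))
  # unconstrained inversion of a drifted target is asymmetric
  expect_gt(max(abs(b$upper + b$lower)[reg]), 0.02)
})

test_that("symmetric inversion nearly coincides with unconstrained at zero drift", {
  ev <- ev_std()
  target <- solve_fpt(bounds_exp(n_steps = 200), ev)
  fu <- invert_boundaries(target, ev, inversion_config())
  fs <- invert_symmetric(target, ev, inversion_config())
  reg <- mass_region(target, 0.05, 0.80)
  expect_lt(max(abs(fu$bounds$upper[reg] - fs$bounds$upper[reg])), 0.02)
  expect_equal(fs$bounds$upper, -fs$bounds$lower)
})

test_that("the symmetry constraint costs accuracy when the drift is large", {
  target <- accumulator_fpt(acc_spec(0.05, 0.1), 300)
  ev <- evidence(0.05, 0.1, 0.01)
  fu <- piecewise_refine(invert_boundaries(target, ev, inversion_config()))
  fs <- piecewise_refine(invert_symmetric(target, ev, inversion_config()))
  expect_gt(fs$objective, fu$objective)
})

test_that("candidate grids rescale with free starting values", {
  ev <- evidence(0, 0.01, 0.01)
  truth <- boundary_from_fun(function(t) 0.1 * exp(-t),
                             function(t) -0.1 * exp(-t), 150, 0.01)
  target <- solve_fpt(truth, ev)
  cfg <- inversion_config(start_upper = 0.1, start_lower = -0.1)
  fit <- invert_boundaries(target, ev, cfg)
  reg <- mass_region(fit$target, 0.05, 0.5)
  expect_lt(max(abs(fit$bounds$upper[reg] - truth$upper[reg])), 0.002)
})

test_that("inversion rejects mismatched step sizes", {
  ev <- ev_std(step = 0.02)
  target <- fpt_dist(c(0.5, 0.5), c(0, 0), 0.01)
  expect_error(invert_boundaries(target, ev, inversion_config(step = 0.01)),
               "same step")
})
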