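test_that("evidence distribution derives drift and diffusion coefficients", {
  ev <- evidence(mu = 0.05, sigma = 0.1, step = 0.01)
  expect_equal(ev$xi, 5)
  expect_equal(ev$s2, 1)
  expect_error(evidence(0, -1, 0.01), "sigma")
  expect_error(evidence(0, 0.1, 0), "step")
})

test_that("boundary tables store starts and backward-difference derivatives", {
  b <- boundary_pair(c(0.9, 0.8), c(-0.9, -0.8), 0.01,
                     start_upper = 1, start_lower = -1)
  d <- boundary_deriv(b)
  expect_equal(d$d_upper, c((0.9 - 1) / 0.01, (0.8 - 0.9) / 0.01))
  expect_equal(d$d_lower, c(10, 10))
  expect_error(boundary_pair(c(1, 1), c(-1, -1), 0.01, start_upper = -1),
               "start")
})

test_that("boundary_open_until finds the first touching step", {
  b <- boundary_pair(c(1, 0.5, 0.1), c(-1, -0.5, 0.2), 0.01,
                     start_upper = 1, start_lower = -1)
  expect_equal(boundary_open_until(b), 2L)
  expect_equal(boundary_open_until(boundary_constant(1, 5, 0.01)), 5L)
})

test_that("fpt_dist enforces non-negativity and near-unit mass", {
  expect_error(fpt_dist(c(-0.1, 0.2), c(0, 0), 0.01), "non-negative")
  expect_error(fpt_dist(c(0.9, 0.2), c(0.1, 0.1), 0.01), "exceeds 1")
  d <- fpt_dist(c(0.5, 0.25), c(0.2, 0.05), 0.01)
  expect_equal(total_mass(d), 1)
  expect_equal(choice_prob(d), 0.75)
})

test_that("renormalize rescales truncated mass and records the truncation", {
  d <- fpt_dist(c(0.4, 0.2), c(0.2, 0.1), 0.01)
  r <- renormalize(d)
  expect_equal(total_mass(r), 1)
  expect_equal(attr(r, "truncated_mass"), 0.1)
  expect_equal(choice_prob(r), choice_prob(d))
})

test_that("total-variation distance matches brute-force enumeration on a toy pair", {
  # 5-step toy distributions compared against direct summation over the
  # completed outcome space (per-step atoms plus the undecided atom)
  a <- fpt_dist(c(0.1, 0.2, 0.1, 0.05, 0.05), c(0.1, 0.1, 0.1, 0.1, 0.1), 1)
  b <- fpt_dist(c(0.3, 0.1, 0.1, 0.0, 0.0), c(0.05, 0.05, 0.2, 0.1, 0.05), 1)
  atoms_a <- c(a$p_upper, a$p_lower, 1 - total_mass(a))
  atoms_b <- c(b$p_upper, b$p_lower, 1 - total_mass(b))
  expect_equal(dist_tv(a, b), sum(abs(atoms_a - atoms_b)) / 2)
  expect_equal(dist_tv(a, a), 0)
  # disjoint supports, both proper -> distance 1
  p <- fpt_dist(c(1, 0), c(0, 0), 1)
  q <- fpt_dist(c(0, 0), c(0, 1), 1)
  expect_equal(dist_tv(p, q), 1)
  expect_error(dist_tv(a, fpt_dist(0.5, 0.5, 1)), "horizon|step")
})
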