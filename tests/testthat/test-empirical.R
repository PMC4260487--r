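test_that("shifting subtracts the minimum RT with a 1 ms guard", {
  d <- tibble::tibble(rt = c(0.4, 0.5, 0.9), choice = c("A", "B", "A"))
  s <- shift_rts(d)
  expect_equal(attr(s, "rt_shift"), 0.399)
  expect_equal(s$rt, c(0.001, 0.101, 0.501))
  # idempotent up to the guard
  s2 <- shift_rts(s)
  expect_equal(s2$rt, s$rt, tolerance = 1e-3)
  # rank order preserved
  expect_equal(order(s$rt), order(d$rt))
  expect_error(shift_rts(tibble::tibble(rt = numeric(), choice = character())),
               "non-empty")
})

test_that("weibull fitting recovers simulated parameters", {
  set.seed(21)
  d <- tibble::tibble(rt = rweibull(1e5, 2, 0.3), choice = "A")
  f <- fit_weibull(d, "A")
  expect_lt(abs(f$shape - 2), 0.05)
  expect_lt(abs(f$scale - 0.3), 0.01)
  expect_equal(f$choice_prob, 1)
})

test_that("weibull fit is scale-equivariant", {
  set.seed(22)
  rt <- rweibull(5000, 1.7, 0.4)
  f1 <- fit_weibull(tibble::tibble(rt = rt, choice = "A"), "A")
  f2 <- fit_weibull(tibble::tibble(rt = 3 * rt, choice = "A"), "A")
  # equal up to optimizer tolerance
  expect_equal(f2$shape, f1$shape, tolerance = 1e-3)
  expect_equal(f2$scale, 3 * f1$scale, tolerance = 1e-3)
})

test_that("tiny-sample MLE agrees with an exhaustive likelihood grid", {
  set.seed(23)
  rt <- rweibull(12, 1.5, 0.5)
  f <- fit_weibull(tibble::tibble(rt = rt, choice = "A"), "A")
  shapes <- seq(0.3, 4, by = 0.01)
  scales <- seq(0.1, 1.5, by = 0.005)
  ll <- outer(shapes, scales, function(k, b) {
    vapply(seq_along(k), function(i) {
      sum(dweibull(rt, k[[i]], b[[i]], log = TRUE))
    }, numeric(1))
  })
  best <- arrayInd(which.max(ll), dim(ll))
  expect_lt(abs(f$shape - shapes[best[1]]), 0.011)
  expect_lt(abs(f$scale - scales[best[2]]), 0.0051)
})

test_that("fitting requires enough usable records", {
  d <- tibble::tibble(rt = rep(0.5, 12), choice = rep(c("A", "B"), 6))
  expect_error(fit_weibull(d, "A"), "fewer than 10")
  expect_error(fit_weibull(tibble::tibble(rt = rep(0.3, 20), choice = "A"), "A"),
               "degenerate")
})

test_that("discretized targets telescope to the choice probabilities", {
  d <- simulate_weibull_rts(4000, p_choice = 0.6, seed = 31)
  s <- shift_rts(d)
  fa <- fit_weibull(s, "A")
  fb <- fit_weibull(s, "B")
  tg <- build_targets(fa, fb, 0.01, 250)
  expect_true(all(tg$p_upper >= 0) && all(tg$p_lower >= 0))
  expect_equal(sum(tg$p_upper),
               fa$choice_prob * pweibull(2.5, fa$shape, fa$scale),
               tolerance = 1e-12)
  # quadrature oracle: numeric integration of the density per bin
  bins <- sample.int(250, 12)
  for (n in bins) {
    q <- stats::integrate(dweibull, (n - 1) * 0.01, n * 0.01,
                          shape = fa$shape, scale = fa$scale,
                          rel.tol = 1e-12)$value * fa$choice_prob
    expect_lt(abs(tg$p_upper[[n]] - q), 1e-10)
  }
  # halving the step leaves the implied CDF unchanged at shared times
  tg2 <- build_targets(fa, fb, 0.005, 500)
  expect_equal(cumsum(tg$p_upper), cumsum(tg2$p_upper)[seq(2, 500, by = 2)],
               tolerance = 1e-12)
})

test_that("decile chi-square reproduces published worked examples", {
  # statistic 7.14 on 7 df gives p = 0.41 to two decimals
  expect_equal(round(chisq_pvalue(7.14, 7), 2), 0.41)
  expect_equal(round(chisq_pvalue(13.02, 7), 2), 0.07)
  expect_equal(round(chisq_pvalue(4.69, 7), 2), 0.70)
  expect_equal(round(chisq_pvalue(9.01, 7), 2), 0.25)
  expect_equal(round(chisq_pvalue(10.02, 7), 2), 0.19)
  expect_equal(round(chisq_pvalue(10.99, 7), 2), 0.14)
})

test_that("a perfectly balanced decile table gives statistic 0 and p = 1", {
  f <- structure(list(shape = 2, scale = 0.3, shift = 0, choice_prob = 1,
                      choice = "A", n = 100), class = "weibull_fit")
  rt <- qweibull(seq(0.005, 0.995, length.out = 100), 2, 0.3)
  d <- tibble::tibble(rt = rt, choice = "A")
  g <- chi_square_gof(d, f)
  expect_equal(g$statistic, 0)
  expect_equal(g$p_value, 1)
  expect_equal(g$dof, 7L)
})

test_that("chi-square machinery matches a brute-force oracle on simulated data", {
  set.seed(41)
  for (i in 1:200) {
    n <- sample(60:200, 1)
    k <- runif(1, 1, 3); b <- runif(1, 0.2, 0.6)
    rt <- rweibull(n, k, b)
    f <- structure(list(shape = k, scale = b, shift = 0, choice_prob = 1,
                        choice = "A", n = n), class = "weibull_fit")
    g <- chi_square_gof(tibble::tibble(rt = rt, choice = "A"), f)
    # oracle: explicit bin counting plus incomplete-gamma series CDF
    edges <- qweibull(seq(0.1, 0.9, 0.1), k, b)
    counts <- vapply(1:10, function(j) {
      lo <- if (j == 1) -Inf else edges[[j - 1]]
      hi <- if (j == 10) Inf else edges[[j]]
      sum(rt > lo & rt <= hi)
    }, numeric(1))
    stat <- sum((counts - n / 10)^2 / (n / 10))
    expect_equal(g$statistic, stat, tolerance = 1e-10)
    expect_equal(g$p_value, chisq_upper_series(stat, 7), tolerance = 1e-10)
  }
})

test_that("the empirical pipeline recovers a known collapsing boundary", {
  ev_true <- evidence(0, 0.01, 0.01)
  truth <- boundary_from_fun(function(t) 0.1 * exp(-t),
                             function(t) -0.1 * exp(-t), 200, 0.01)
  d <- simulate_diffusion_rts(truth, ev_true, n_trials = 6000, shift = 0.3,
                              seed = 11)
  res <- fit_boundaries_empirical(d, n_start = 8)
  fit <- res$fit
  cum <- cumsum(fit$target$p_upper + fit$target$p_lower)
  reg <- which(cum >= 0.05 & cum <= 0.95)
  reg <- reg[reg <= nrow(truth)]
  expect_gt(cor(fit$bounds$upper[reg], truth$upper[reg]), 0.9)
  expect_gt(cor(fit$bounds$lower[reg], truth$lower[reg]), 0.9)
  expect_lt(fit$tv, 0.05)
  expect_gt(res$shift, 0.29)  # the non-decision shift is found (upward biased)
})

test_that("symmetric and unconstrained empirical fits nearly coincide on symmetric data", {
  d <- simulate_weibull_rts(3000, p_choice = 0.5, seed = 55)
  ru <- fit_boundaries_empirical(d, n_start = 5)
  rs <- fit_boundaries_empirical(d, n_start = 5, symmetric = TRUE)
  reg <- mass_region(ru$target, 0.1, 0.9)
  su <- attr(ru$fit$bounds, "start_upper")
  expect_lt(max(abs(ru$fit$bounds$upper[reg] - rs$fit$bounds$upper[reg])),
            0.25 * su)
  expect_lt(rs$fit$tv, 0.08)
})

test_that("a slower subject's boundaries begin their descent later", {
  ev_true <- evidence(0, 0.01, 0.01)
  fast <- boundary_from_fun(function(t) 0.08 * exp(-t / 0.4),
                            function(t) -0.08 * exp(-t / 0.4), 250, 0.01)
  slow <- boundary_from_fun(function(t) 0.08 * pmin(1, exp(-(t - 0.5) / 0.4)),
                            function(t) -0.08 * pmin(1, exp(-(t - 0.5) / 0.4)),
                            250, 0.01)
  df <- simulate_diffusion_rts(fast, ev_true, 5000, shift = 0.3, seed = 61)
  ds <- simulate_diffusion_rts(slow, ev_true, 5000, shift = 0.3, seed = 62)
  expect_lt(mean(df$rt), mean(ds$rt))
  rf <- fit_boundaries_empirical(df, n_start = 6)
  rs <- fit_boundaries_empirical(ds, n_start = 6)
  # onset of descent: first step where the recovered upper boundary falls
  # below half its maximum level (the start value itself is only weakly
  # identified, the in-region level profile is what the data pin down)
  onset <- function(fit) {
    b <- fit$bounds$upper
    which(b < 0.5 * max(b))[[1]]
  }
  expect_lt(onset(rf$fit), onset(rs$fit))
})
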