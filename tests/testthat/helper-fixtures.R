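# shared builders for small test problems

ev_std <- function(mu = 0, sigma = 0.1, step = 0.01) evidence(mu, sigma, step)

bounds_exp <- function(a0 = 1, rate = 1, n_steps = 300, step = 0.01) {
  boundary_from_fun(function(t) a0 * exp(-rate * t),
                    function(t) -a0 * exp(-rate * t), n_steps, step)
}

# central region holding the stated share of decision mass
mass_region <- function(dist, lo = 0.025, hi = 0.975) {
  cum <- cumsum(dist$p_upper + dist$p_lower)
  which(cum >= lo & cum <= hi)
}

pad_dist_for_test <- function(d, n) tvbounds:::pad_dist(d, n)

# independent trapezoid quadrature (used as an oracle for densities)
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# upper-tail chi-squared p-value via the regularized incomplete gamma series,
# written independently of stats::pchisq (oracle for chi_square_gof)
chisq_upper_series <- function(x, dof) {
  # P(X > x) = 1 - P(a, x/2) with a = dof/2, by the standard power series
  a <- dof / 2
  z <- x / 2
  if (z <= 0) return(1)
  term <- exp(-z + a * log(z) - lgamma(a + 1))
  total <- term
  k <- 1
  while (term > 1e-18 && k < 10000) {
    term <- term * z / (a + k)
    total <- total + term
    k <- k + 1
  }
  max(0, 1 - total)
}
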