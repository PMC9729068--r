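test_that("the per-locus sampling probability behaves at its limits", {
  # t = 0: identical sequences with probability 1
  expect_equal(prob_x_given_t(0, n = 100, t = 0), 1)
  expect_equal(prob_x_given_t(1:5, n = 100, t = 0), rep(0, 5))
  # saturation: Binomial(n, 3/4)
  expect_equal(prob_x_given_t(0:50, n = 50, t = 100),
               dbinom(0:50, 50, 0.75), tolerance = 1e-12)
  # normalisation for both mutation models
  expect_equal(sum(prob_x_given_t(0:1000, 1000, 0.005)), 1,
               tolerance = 1e-12)
  expect_equal(sum(prob_x_given_t(0:200, 1000, 0.005, "poisson")), 1,
               tolerance = 1e-12)
  expect_error(prob_x_given_t(11, n = 10, t = 0.01), "exceed")
})

test_that("marginal probabilities are normalised for all four models", {
  for (p in list(fig1_im(), fig1_iim(), fig1_sc(), msci_truth())) {
    lp <- marginal_log_pmf(0:1000, 1000, p, "binomial_jc")
    expect_equal(sum(exp(lp)), 1, tolerance = 1e-8)
    lpp <- marginal_log_pmf(0:400, 1000, p, "poisson")
    expect_equal(sum(exp(lpp)), 1, tolerance = 1e-8)
  }
})

test_that("closed-form Poisson marginals agree with adaptive quadrature to 1e-10", {
  x <- c(0:10, 20, 40)
  for (p in list(fig1_im(), fig1_iim(), fig1_sc(), msci_truth())) {
    cf <- marginal_prob_x(x, 1000, p, "poisson", "closed_form")
    qd <- marginal_prob_x(x, 1000, p, "poisson", "quadrature")
    expect_lt(max(abs(cf - qd)), 1e-10)
  }
  expect_lt(abs(marginal_prob_x(3, 1000, fig1_iim(), "poisson", "closed_form") -
                  marginal_prob_x(3, 1000, fig1_iim(), "poisson", "quadrature")),
            1e-10)
  expect_error(marginal_prob_x(3, 1000, fig1_im(), "binomial_jc",
                               "closed_form"), "poisson")
})

test_that("the shared-node fast path matches adaptive quadrature, including near-point-mass pieces", {
  x <- 0:40
  for (p in list(fig1_im(), fig1_iim(), fig1_sc(), msci_truth())) {
    fast <- exp(marginal_log_pmf(x, 1000, p, "binomial_jc"))
    slow <- marginal_prob_x(x, 1000, p, "binomial_jc", "quadrature")
    expect_lt(max(abs(fast - slow)), 1e-10)
  }
  spike <- msci_params(0.004, 0.002, 0.01, 1e-6, phi = 0.2)
  expect_equal(sum(exp(marginal_log_pmf(0:1000, 1000, spike))), 1,
               tolerance = 1e-8)
})

test_that("log-space evaluation survives very long sequences", {
  lp <- marginal_log_pmf(c(0, 100, 400, 900), 64000, fig1_im(),
                         "binomial_jc")
  expect_true(all(is.finite(lp)))
  expect_equal(sum(exp(marginal_log_pmf(0:8000, 64000, fig1_im()))), 1,
               tolerance = 1e-6)
})

test_that("Poisson and binomial marginals converge as n grows", {
  # sup-norm distance between the two mutation models decreases in n
  p <- fig1_im()
  dists <- vapply(c(250, 1000, 4000), function(n) {
    x <- 0:round(n * 0.1)
    max(abs(exp(marginal_log_pmf(x, n, p, "binomial_jc")) -
              exp(marginal_log_pmf(x, n, p, "poisson"))))
  }, 0)
  expect_true(all(diff(dists) < 0))
})

test_that("empirical difference counts match the marginal pmf", {
  p <- fig1_sc()
  n <- 500
  withr::with_seed(5, {
    counts <- simulate_locus_counts(p, L = 1e5, n = n)
  })
  obs <- tabulate(counts$x + 1L, nbins = n + 1L)
  expected <- 1e5 * exp(marginal_log_pmf(0:n, n, p, "binomial_jc"))
  # chi-square over bins with decent expected counts
  keep <- expected >= 5
  chisq <- sum((obs[keep] - expected[keep])^2 / expected[keep]) +
    (sum(obs[!keep]) - sum(expected[!keep]))^2 / max(sum(expected[!keep]), 1)
  df <- sum(keep)
  expect_gt(pchisq(chisq, df, lower.tail = FALSE), 0.01)
})
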