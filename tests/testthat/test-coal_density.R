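test_that("transition matrix is the identity at t = 0 and stays stochastic", {
  expect_equal(transition_matrix(80, 0.002, 0), diag(3), ignore_attr = TRUE)
  withr::with_seed(1, {
    for (i in 1:25) {
      w <- runif(1, 0, 2000)
      thA <- runif(1, 1e-4, 0.05)
      t <- runif(1, 0, 0.05)
      P <- transition_matrix(w, thA, t)
      expect_equal(unname(rowSums(P)), c(1, 1, 1), tolerance = 1e-12)
      expect_true(all(P >= 0 & P <= 1 + 1e-12))
    }
  })
  expect_error(transition_matrix(-1, 0.002, 0.01), ">=")
})

test_that("closed-form transition matrix equals the matrix exponential, including near w = 2/thetaA", {
  skip_if_not_installed("Matrix")
  check_against_expm <- function(w, thA, t) {
    P <- transition_matrix(w, thA, t)
    Q <- mscm_generator(w, thA)
    Pe <- as.matrix(Matrix::expm(Q * t))
    expect_lt(max(abs(P - Pe)), 1e-10)
  }
  check_against_expm(80, 0.002, 0.002)
  withr::with_seed(2, {
    for (i in 1:20) {
      check_against_expm(runif(1, 0, 2000), runif(1, 1e-4, 0.05),
                         runif(1, 0, 0.05))
    }
  })
  # removable singularity: w approaching and hitting 2/thetaA
  thA <- 0.002
  for (eps in c(1e-3, 1e-6, 1e-9, 0)) {
    check_against_expm(2 / thA * (1 + eps), thA, 0.003)
  }
})

test_that("Chapman-Kolmogorov holds: P(s + t) = P(s) P(t)", {
  withr::with_seed(3, {
    for (i in 1:10) {
      w <- runif(1, 0, 500); thA <- runif(1, 1e-3, 0.05)
      s <- runif(1, 0, 0.02); t <- runif(1, 0, 0.02)
      lhs <- transition_matrix(w, thA, s + t)
      rhs <- transition_matrix(w, thA, s) %*% transition_matrix(w, thA, t)
      expect_lt(max(abs(lhs - rhs)), 1e-10)
    }
  })
})

test_that("all model densities integrate to one over a randomised grid", {
  for (p in random_mscm_grid(12)) {
    d <- coal_density(p)
    expect_equal(misflow:::integrate_density(d), 1, tolerance = 1e-8)
  }
  for (p in random_msci_grid(8)) {
    d <- coal_density(p)
    expect_equal(misflow:::integrate_density(d), 1, tolerance = 1e-8)
  }
})

test_that("IIM with tauT = 0 is the IM density; the density depends on M, thetaB only via w", {
  im <- fig1_im()
  iim0 <- mscm_params("iim", tauR = im$tauR, tauT = 0, thetaA = im$thetaA,
                      thetaB = im$thetaB, thetaR = im$thetaR, M = im$M)
  tgrid <- seq(0, 0.02, length.out = 200)
  expect_equal(density_mscm(tgrid, iim0), density_mscm(tgrid, im))

  # same w via different (M, thetaB) pairs
  p1 <- mscm_params("im", tauR = 0.002, thetaA = 0.002, thetaB = 0.01,
                    thetaR = 0.01, M = 0.2)
  p2 <- mscm_params("im", tauR = 0.002, thetaA = 0.002, thetaB = 0.02,
                    thetaR = 0.01, M = 0.4)
  expect_equal(density_mscm(tgrid, p1), density_mscm(tgrid, p2))
})

test_that("with no gene flow the density is a shifted exponential beyond tauR", {
  p <- mscm_params("im", tauR = 0.002, thetaA = 0.002, thetaB = 0.01,
                   thetaR = 0.01, M = 0)
  tgrid <- seq(0, 0.0019, length.out = 50)
  expect_equal(density_mscm(tgrid, p), rep(0, 50))
  t2 <- seq(0.0021, 0.02, length.out = 50)
  expect_equal(density_mscm(t2, p),
               (2 / 0.01) * exp(-2 * (t2 - 0.002) / 0.01))
})

test_that("the introgression density follows its closed form piece by piece", {
  # phi = 1: pure donor-segment exponential between tauS and tauR
  p1 <- msci_params(0.004, 0.002, 0.01, 0.002, phi = 1)
  tgrid <- seq(0.0021, 0.0039, length.out = 50)
  expect_equal(density_msci(tgrid, p1),
               (2 / 0.002) * exp(-2 * (tgrid - 0.002) / 0.002))
  # phi = 0: all mass beyond tauR
  p0 <- msci_params(0.004, 0.002, 0.01, 0.002, phi = 0)
  expect_equal(density_msci(seq(0, 0.0039, length.out = 50), p0), rep(0, 50))
  # zero below the minimum coalescent time
  p <- msci_params(0.004, 0.002, 0.01, 0.002, phi = 0.2)
  expect_equal(density_msci(c(0, 0.001, 0.00199), p), rep(0, 3))
})

test_that("the SC density is continuous at tauT and discontinuous only at tauR; IIM is zero before tauT", {
  sc <- fig1_sc()
  eps <- 1e-10
  expect_equal(density_mscm(sc$tauT - eps, sc), density_mscm(sc$tauT + eps, sc),
               tolerance = 1e-6)
  jump <- abs(density_mscm(sc$tauR + eps, sc) - density_mscm(sc$tauR - eps, sc))
  expect_gt(jump, 1)

  iim <- fig1_iim()
  expect_equal(density_mscm(seq(0, iim$tauT - 1e-9, length.out = 20), iim),
               rep(0, 20))
})

test_that("density moments match closed forms and a Monte-Carlo oracle", {
  # isolation limits: mean = tauR + thetaR / 2
  m0 <- density_moments(coal_density(msci_params(0.004, 0.002, 0.01, 0.002,
                                                 phi = 0)))
  expect_equal(m0$mean, 0.004 + 0.01 / 2, tolerance = 1e-8)
  p_iso <- mscm_params("im", tauR = 0.002, thetaA = 0.002, thetaB = 0.01,
                       thetaR = 0.01, M = 0)
  expect_equal(density_moments(coal_density(p_iso))$mean, 0.002 + 0.005,
               tolerance = 1e-8)

  # simulator oracle for the fig1 IM preset
  withr::with_seed(11, {
    tt <- simulate_coal_times(fig1_im(), 4e4)
  })
  m <- density_moments(coal_density(fig1_im()))
  se <- sd(tt) / sqrt(length(tt))
  expect_lt(abs(mean(tt) - m$mean), 3 * se)

  # refuses non-normalised input
  d <- coal_density(fig1_im())
  d$pieces[[1]] <- function(t) rep(0, length(t))
  expect_error(density_moments(d), "integrates")
})

test_that("the distribution function matches numeric integration of the density", {
  for (p in list(fig1_im(), fig1_iim(), fig1_sc(), msci_truth())) {
    d <- coal_density(p)
    for (q in c(0.001, 0.003, 0.006, 0.02)) {
      expect_equal(pcoal(q, d),
                   misflow:::integrate_density(d, upper = q),
                   tolerance = 1e-8)
    }
    expect_equal(pcoal(1, d), 1, tolerance = 1e-8)
  }
})
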