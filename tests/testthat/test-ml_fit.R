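test_that("the log-likelihood is additive over loci and matches per-locus quadrature", {
  m <- msci_truth()
  counts <- simulate_locus_counts(m, L = 50, n = 500, seed = 11)
  ll <- coal_loglik(m, counts)
  expect_equal(as.numeric(coal_loglik(m, rbind(counts, counts))),
               2 * as.numeric(ll), tolerance = 1e-12)
  # quadrature oracle, locus by locus
  direct <- sum(log(vapply(seq_len(nrow(counts)), function(i) {
    marginal_prob_x(counts$x[i], counts$n[i], m, "binomial_jc",
                    "quadrature")
  }, 0)))
  expect_equal(as.numeric(ll), direct, tolerance = 1e-6)
  # any (x, n) has positive probability under phi = 0
  m0 <- msci_truth(phi = 0)
  expect_true(is.finite(coal_loglik(m0, data.frame(x = c(0, 499), n = 500))))
})

test_that("maximum likelihood recovers the generating introgression parameters", {
  truth <- msci_truth()
  counts <- simulate_locus_counts(truth, L = 4000, n = 1000, seed = 12)
  withr::with_seed(12, {
    fit <- fit_ml(counts, "msci", spec = "b", gen = truth, restarts = 2)
  })
  td <- tidy(fit)
  for (term in c("tauR", "tauS", "phi")) {
    row <- td[td$term == term, ]
    truth_val <- truth[[term]]
    expect_lt(abs(row$estimate - truth_val), 3 * row$std.error)
  }
  expect_true(glance(fit)$converged)
})

test_that("estimates under the misspecified model track the pseudo-true values as L grows", {
  im <- fig1_im()
  withr::with_seed(13, {
    pt <- minimize_kl(im, "b", n = 1000, restarts = 2)
    phis <- vapply(c(1e3, 1e4), function(L) {
      counts <- simulate_locus_counts(im, L, n = 1000)
      fit_ml(counts, "msci", spec = "b", gen = im, restarts = 2)$estimates$phi
    }, 0)
  })
  err <- abs(phis - pt$estimates$phi)
  expect_lt(err[2], err[1])
  # below the expected total migrant fraction once sampling noise is tamed
  expect_lt(phis[2], phi0(im$M, im$tauR, im$thetaB))
})

test_that("standard errors shrink like the square root of the number of loci", {
  truth <- msci_truth()
  se_phi <- function(L) {
    counts <- simulate_locus_counts(truth, L, n = 1000)
    fit <- fit_ml(counts, "msci", spec = "b", gen = truth, restarts = 1)
    td <- tidy(fit)
    td$std.error[td$term == "phi"]
  }
  withr::with_seed(14, {
    se_small <- vapply(1:6, function(i) se_phi(1000), 0)
    se_big <- vapply(1:6, function(i) se_phi(4000), 0)
  })
  ratio <- mean(se_big) / mean(se_small)  # L quadrupled: expect ~1/2
  expect_gt(ratio, 0.4)
  expect_lt(ratio, 0.65)
})

test_that("fit comparison tables are well-formed and favour the generating model family", {
  # a high migration rate separates the model families enough that the
  # expected dominance of the generating family shows through the
  # sampling noise of a single dataset
  im <- fig1_im(); im$M <- 1.5
  counts <- simulate_locus_counts(im, 2000, n = 500, seed = 15)
  withr::with_seed(15, {
    fit_i <- fit_ml(counts, "im", restarts = 4)
    fit_m <- fit_ml(counts, "msci", spec = "b", gen = im, restarts = 2)
  })
  tab <- compare_fits(list(fit_i, fit_m))
  expect_equal(nrow(tab), 2)
  expect_equal(max(tab$delta_logLik), 0)
  # the correctly specified migration model fits at least as well
  expect_gte(tab$logLik[tab$model == "im"],
             tab$logLik[tab$model == "msci"] - 1e-6)

  one <- compare_fits(list(fit_m))
  expect_equal(nrow(one), 1)
  expect_equal(one$delta_logLik, 0)

  # flat table round-trips through TSV
  tmp <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- utils::read.table(tmp, header = TRUE, sep = "\t")
  expect_equal(back$logLik, tab$logLik, tolerance = 1e-8)

  fit_other <- fit_ml(simulate_locus_counts(im, 100, n = 500, seed = 1),
                      "msci", spec = "b", gen = im, restarts = 1)
  expect_error(compare_fits(list(fit_i, fit_other)), "different")
})
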