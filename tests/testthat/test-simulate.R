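test_that("isolation forces coalescence beyond the divergence time", {
  p <- mscm_params("im", tauR = 0.002, thetaA = 0.002, thetaB = 0.01,
                   thetaR = 0.01, M = 0)
  withr::with_seed(1, tt <- simulate_coal_times(p, 5000))
  expect_true(all(tt > p$tauR))

  net <- as_species_network(p)
  withr::with_seed(2, {
    h <- replicate(200, max(ape::node.depth.edgelength(
      simulate_gene_tree(net))))
  })
  expect_true(all(h > p$tauR))
})

test_that("simulated coalescent times match the analytic densities (KS)", {
  L <- 2e4
  models <- list(im = fig1_im(), iim = fig1_iim(), sc = fig1_sc(),
                 msci = msci_truth())
  withr::with_seed(3, {
    for (nm in names(models)) {
      tt <- simulate_coal_times(models[[nm]], L)
      d <- coal_density(models[[nm]])
      ks <- suppressWarnings(ks.test(tt, function(q) pcoal(q, d)))
      expect_gt(ks$p.value, 0.01)
    }
  })
})

test_that("the network simulator agrees with the direct two-species sampler", {
  withr::with_seed(4, {
    for (p in list(fig1_iim(), msci_truth())) {
      net <- as_species_network(p)
      tg <- replicate(1500, max(ape::node.depth.edgelength(
        simulate_gene_tree(net))))
      tf <- simulate_coal_times(p, 1500)
      expect_gt(suppressWarnings(ks.test(tg, tf))$p.value, 0.01)
    }
  })
})

test_that("introgression sends lineages through the donor path at rate phi", {
  m <- msci_truth(phi = 0.3)
  net <- as_species_network(m)
  withr::with_seed(5, {
    took <- replicate(2000, {
      tr <- simulate_gene_tree(net)
      attr(tr, "introgressed")[["B_1"]]
    })
  })
  p_hat <- mean(took)
  se <- sqrt(0.3 * 0.7 / 2000)
  expect_lt(abs(p_hat - 0.3), 3 * se)
})

test_that("band jump counts follow the exposure probability", {
  # in the IM model the B lineage can jump at most once and is exposed to
  # the band over (0, tauR): P(jump) = 1 - exp(-w tauR)
  p <- fig1_im()
  w <- migration_rate_scaled(p)
  p_jump <- -expm1(-w * p$tauR)
  net <- as_species_network(p)
  withr::with_seed(6, {
    jumps <- replicate(2000, attr(simulate_gene_tree(net), "migrations"))
  })
  expect_true(all(jumps <= 1))
  se <- sqrt(p_jump * (1 - p_jump) / 2000)
  expect_lt(abs(mean(jumps) - p_jump), 3 * se)
})

test_that("Jukes-Cantor sequence evolution has the right pairwise behaviour", {
  # zero branch lengths: identical sequences
  p <- msci_truth()
  net <- as_species_network(p)
  withr::with_seed(7, tr <- simulate_gene_tree(net))
  tr0 <- tr; tr0$edge.length[] <- 0
  aln0 <- evolve_sequences_jc(tr0, 200)
  expect_equal(aln0["A_1", ], aln0["B_1", ])

  # divergence t: mismatch fraction ~ 3/4 (1 - e^{-8t/3})
  two_tip <- ape::read.tree(text = "(a:0.01,b:0.01);")
  withr::with_seed(8, aln <- evolve_sequences_jc(two_tip, 2e4))
  pt <- 0.75 * (1 - exp(-8 * 0.01 / 3))
  obs <- pairwise_diff_counts(aln, c("a", "b"))
  se <- sqrt(pt * (1 - pt) / 2e4)
  expect_lt(abs(obs$x / obs$n - pt), 3 * se)

  # saturation at 3/4
  long <- ape::read.tree(text = "(a:3,b:3);")
  withr::with_seed(9, alnL <- evolve_sequences_jc(long, 2e4))
  obsL <- pairwise_diff_counts(alnL, c("a", "b"))
  expect_lt(abs(obsL$x / obsL$n - 0.75), 3 * sqrt(0.75 * 0.25 / 2e4))
})

test_that("pairwise difference counting is exact on toy alignments", {
  aln <- rbind(a = c("A", "A", "A", "A"), b = c("A", "A", "A", "T"))
  expect_equal(pairwise_diff_counts(aln, c("a", "b")),
               tibble::tibble(x = 1L, n = 4L), ignore_attr = TRUE)
  expect_equal(pairwise_diff_counts(rbind(a = rep("C", 6),
                                          b = rep("C", 6)))$x, 0L)
  expect_error(pairwise_diff_counts(list(a = c("A"), b = c("A", "C"))),
               "length")
})

test_that("datasets are deterministic under a fixed seed and have the right shape", {
  sc <- preset_scenario("fig1-im", L = 6, S = 1, n = 120)
  d1 <- simulate_dataset(sc, seed = 99)
  d2 <- simulate_dataset(sc, seed = 99)
  expect_identical(d1$loci, d2$loci)
  expect_length(d1$loci, 6)
  expect_true(all(vapply(d1$loci, function(a) all(dim(a) == c(2, 120)),
                         TRUE)))
  # extending L leaves earlier loci untouched
  sc2 <- preset_scenario("fig1-im", L = 9, S = 1, n = 120)
  d3 <- simulate_dataset(sc2, seed = 99)
  expect_identical(d3$loci[1:6], d1$loci)

  cnt <- simulate_dataset(sc, seed = 99, output = "counts")
  expect_equal(nrow(cnt$loci), 6)
  expect_true(all(cnt$loci$x <= cnt$loci$n))
})

test_that("gene flow from divergence until a stop time is an isolation-with-migration process shifted in time", {
  # with one pair per locus, the IIM history is the IM history translated
  # by the gene-flow stop time
  iim <- fig1_iim()
  withr::with_seed(10, {
    t_iim <- simulate_coal_times(iim, 4000) - iim$tauT
    t_im <- simulate_coal_times(fig1_im(), 4000)
  })
  expect_gt(suppressWarnings(ks.test(t_iim, t_im))$p.value, 0.01)
})

test_that("the ghost donor's population size leaves the single-pair margin untouched", {
  # only one sampled lineage can ever transit the unsampled donor branch,
  # so its theta cannot affect the (a, b) coalescent-time margin
  full <- preset_scenario("fig7-ghost-intro")$network
  fat <- full
  fat$nodes$theta[fat$nodes$label == "U"] <-
    5 * fat$nodes$theta[fat$nodes$label == "U"]
  one <- c(A = 1L, B = 1L, C = 1L)
  pair_time <- function(net) {
    tr <- simulate_gene_tree(net, samples = one)
    d <- ape::cophenetic.phylo(tr)
    d["A_1", "B_1"] / 2
  }
  withr::with_seed(19, {
    t_full <- replicate(1200, pair_time(full))
    t_fat <- replicate(1200, pair_time(fat))
  })
  expect_gt(suppressWarnings(ks.test(t_full, t_fat))$p.value, 0.01)
})

test_that("full sequence simulation reproduces the analytic difference-count marginal", {
  sc <- preset_scenario("fig1-im", L = 400, S = 1, n = 250)
  d <- simulate_dataset(sc, seed = 3, output = "counts")
  lp <- marginal_log_pmf(0:250, 250, sc$params, "binomial_jc")
  expected <- 400 * exp(lp)
  obs <- tabulate(d$loci$x + 1L, nbins = 251)
  keep <- expected >= 5
  chisq <- sum((obs[keep] - expected[keep])^2 / expected[keep]) +
    (sum(obs[!keep]) - sum(expected[!keep]))^2 / sum(expected[!keep])
  expect_gt(pchisq(chisq, sum(keep), lower.tail = FALSE), 0.01)
})

test_that("multilocus writers emit parseable files", {
  sc <- preset_scenario("fig1-im", L = 3, S = 2, n = 60)
  d <- simulate_dataset(sc, seed = 5)
  tmp <- withr::local_tempfile(fileext = ".txt")
  write_phylip(d, tmp)
  first <- readLines(tmp, n = 1)
  expect_equal(first, "4 60")

  tmpf <- withr::local_tempfile(fileext = ".fa")
  write_fasta(d, tmpf)
  expect_equal(sum(startsWith(readLines(tmpf), ">")), 12)

  cnt <- simulate_locus_counts(fig1_im(), 20, 100, seed = 1)
  tmpc <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(cnt, tmpc)
  back <- read_counts_tsv(tmpc)
  expect_equal(back$x, cnt$x)
  expect_equal(back$n, cnt$n)

  tmpt <- withr::local_tempfile(fileext = ".nwk")
  withr::with_seed(6, {
    trees <- replicate(2, simulate_gene_tree(
      as_species_network(fig1_im())), simplify = FALSE)
  })
  write_gene_trees(trees, tmpt)
  reread <- ape::read.tree(tmpt)
  expect_length(reread, 2)
})
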