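#' Simulate pairwise coalescent times under the two-species models
#'
#' Exact process-level sampler for the coalescent time between one sequence
#' from each species, implemented as the competing-exponentials backward
#' process (migration of the B lineage into A at rate `w = 4 M / thetaB`,
#' coalescence at rate `2 / theta` of the current population, epochs advancing
#' at the model's change points). It is fully vectorised over loci and does
#' not use the analytic densities, so it serves as an independent check of
#' them.
#'
#' @param params An [mscm_params()] or [msci_params()] object.
#' @param L Number of independent replicates (loci).
#' @return Numeric vector of `L` coalescent times.
#' @examples
#' set.seed(1)
#' t <- simulate_coal_times(preset_scenario("fig1-im")$params, 1000)
#' @export
simulate_coal_times <- function(params, L) {
  L <- check_count(L, "L")
  if (inherits(params, "msci_params")) {
    stop_if_invalid(params)
    jump <- runif(L) < params$phi
    t <- numeric(L)
    # with prob phi the B lineage enters the donor segment S at tauS and may
    # coalesce there before tauR; otherwise both lineages first meet in R
    t_s <- params$tauS + rexp(L, rate = 2 / params$thetaS)
    in_s <- jump & t_s < params$tauR
    t[in_s] <- t_s[in_s]
    t[!in_s] <- params$tauR + rexp(sum(!in_s), rate = 2 / params$thetaR)
    return(t)
  }
  stopifnot(inherits(params, "mscm_params"))
  stop_if_invalid(params)
  w <- migration_rate_scaled(params)
  aR <- 2 / params$thetaR
  aA <- 2 / params$thetaA
  t <- numeric(L)
  if (params$variant %in% c("im", "iim")) {
    t_mig <- params$tauT + rexp_safe(L, w)
    mig <- t_mig < params$tauR
    t_coal <- t_mig + rexp(L, aA)
    early <- mig & t_coal < params$tauR
    t[early] <- t_coal[early]
    t[!early] <- params$tauR + rexp(sum(!early), aR)
  } else {
    t_mig <- rexp_safe(L, w)
    mig <- t_mig < params$tauT
    t_coal <- t_mig + rexp(L, aA)
    early <- mig & t_coal < params$tauR
    t[early] <- t_coal[early]
    t[!early] <- params$tauR + rexp(sum(!early), aR)
  }
  t
}

rexp_safe <- function(L, rate) {
  if (rate <= 0) rep(Inf, L) else rexp(L, rate)
}

#' Simulate a gene tree on a species network
#'
#' Event-driven backward-in-time structured coalescent. Within each epoch
#' (delimited by node ages, migration-band endpoints and introgression
#' times), lineage pairs in a population coalesce at rate `2 / theta` and
#' each lineage in an active band's recipient branch jumps to the donor at
#' rate `4 M / theta_recipient`; the next event is drawn from the competing
#' exponentials and truncated at the epoch boundary. At an introgression
#' event, every lineage in the recipient branch independently moves to the
#' donor with probability `phi`. At a species-tree node, lineages in the
#' child branches merge into the parent branch.
#'
#' @param net A valid [species_network()].
#' @param samples Named integer vector overriding `net$samples`.
#' @return An [ape::phylo] gene tree whose tip labels are
#'   `<species>_<index>`, with branch lengths in expected mutations per
#'   site, plus attributes `migrations` (number of band jumps) and
#'   `introgressed` (named logical: which tips took an introgression edge at
#'   least once).
#' @examples
#' set.seed(1)
#' tr <- simulate_gene_tree(preset_scenario("fig4-C")$network)
#' @export
simulate_gene_tree <- function(net, samples = NULL) {
  stopifnot(inherits(net, "species_network"))
  v <- validate_params(net)
  if (nrow(v)) {
    abort(paste0("invalid network: ",
                 paste(sprintf("%s (%s)", v$field, v$rule), collapse = "; ")))
  }
  if (is.null(samples)) samples <- net$samples
  samples <- samples[samples > 0]
  if (!length(samples)) abort("no samples to simulate")
  nodes <- net$nodes
  theta_of <- setNames(nodes$theta, nodes$label)
  age_of <- setNames(nodes$age, nodes$label)
  parent_of <- setNames(nodes$parent, nodes$label)

  tip_species <- rep(names(samples), as.integer(samples))
  tip_labels <- unlist(lapply(names(samples), function(sp) {
    paste0(sp, "_", seq_len(samples[[sp]]))
  }))
  N <- length(tip_labels)

  lin_pop <- tip_species           # current branch of each live lineage
  lin_node <- seq_len(N)           # tree-node id carried by each lineage
  node_age <- rep(0, N)            # age of every created tree node
  merges <- list()                 # (id, left, right)
  next_id <- N
  migrations <- 0L
  introgressed <- setNames(rep(FALSE, N), tip_labels)

  boundaries <- sort(unique(c(
    nodes$age[nodes$age > 0],
    net$bands$t_start, net$bands$t_end,
    net$events$time)))
  boundaries <- c(boundaries[boundaries > 0], Inf)

  cur <- 0
  b_idx <- 1L
  while (length(lin_node) > 1L) {
    nxt <- boundaries[b_idx]
    repeat {
      pops <- split(seq_along(lin_pop), lin_pop)
      coal_rates <- vapply(pops, function(ix) {
        k <- length(ix)
        if (k < 2) 0 else k * (k - 1) / 2 * 2 / theta_of[[lin_pop[ix[1]]]]
      }, 0)
      active <- net$bands[net$bands$t_start <= cur & net$bands$t_end > cur, ,
                          drop = FALSE]
      mig_rates <- numeric(nrow(active))
      for (bi in seq_len(nrow(active))) {
        k <- sum(lin_pop == active$recipient[bi])
        mig_rates[bi] <- k * 4 * active$M[bi] / theta_of[[active$recipient[bi]]]
      }
      total <- sum(coal_rates) + sum(mig_rates)
      if (total <= 0) { cur <- nxt; break }
      dt <- rexp(1, total)
      if (cur + dt >= nxt) { cur <- nxt; break }
      cur <- cur + dt
      pick <- runif(1, 0, total)
      if (pick <= sum(coal_rates)) {
        pop <- names(coal_rates)[findInterval(pick, cumsum(coal_rates),
                                              left.open = TRUE) + 1L]
        cand <- pops[[pop]]
        ix <- cand[sample.int(length(cand), 2L)]
        next_id <- next_id + 1L
        merges[[length(merges) + 1L]] <-
          c(next_id, lin_node[ix[1]], lin_node[ix[2]])
        node_age[next_id] <- cur
        lin_node[ix[1]] <- next_id
        lin_node <- lin_node[-ix[2]]
        lin_pop <- lin_pop[-ix[2]]
      } else {
        pick <- pick - sum(coal_rates)
        bi <- findInterval(pick, cumsum(mig_rates), left.open = TRUE) + 1L
        cand <- which(lin_pop == active$recipient[bi])
        ix <- cand[sample.int(length(cand), 1L)]
        lin_pop[ix] <- active$donor[bi]
        migrations <- migrations + 1L
      }
      if (length(lin_node) == 1L) break
    }
    if (length(lin_node) == 1L || !is.finite(cur)) break
    # boundary processing: introgression first, then branch merges
    ev <- net$events[net$events$time == cur, , drop = FALSE]
    for (ei in seq_len(nrow(ev))) {
      in_rec <- which(lin_pop == ev$recipient[ei])
      if (length(in_rec)) {
        go <- in_rec[runif(length(in_rec)) < ev$phi[ei]]
        lin_pop[go] <- ev$donor[ei]
        if (length(go)) {
          affected <- unlist(lapply(lin_node[go], tips_below, merges = merges,
                                    N = N))
          introgressed[tip_labels[affected]] <- TRUE
        }
      }
    }
    # lineages in any branch whose top node has age `cur` move to the parent
    movers <- nodes$label[nodes$label %in% lin_pop &
                            !is.na(parent_of[nodes$label]) &
                            age_of[parent_of[nodes$label]] == cur]
    for (lab in movers) lin_pop[lin_pop == lab] <- parent_of[[lab]]
    b_idx <- b_idx + 1L
  }
  tr <- build_phylo(N, tip_labels, merges, node_age)
  attr(tr, "migrations") <- migrations
  attr(tr, "introgressed") <- introgressed
  tr
}

tips_below <- function(id, merges, N) {
  if (id <= N) return(id)
  for (m in merges) {
    if (m[1] == id) {
      return(c(tips_below(m[2], merges, N), tips_below(m[3], merges, N)))
    }
  }
  integer()
}

build_phylo <- function(N, tip_labels, merges, node_age) {
  n_int <- length(merges)
  stopifnot(n_int == N - 1L)
  root_old <- merges[[n_int]][1]
  kids <- list()
  for (m in merges) kids[[as.character(m[1])]] <- m[2:3]
  # preorder renumbering so the root is N + 1
  newid <- integer(N + n_int)
  newid[seq_len(N)] <- seq_len(N)
  counter <- N
  stack <- root_old
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v > N) {
      counter <- counter + 1L
      newid[v] <- counter
      stack <- c(kids[[as.character(v)]], stack)
    }
  }
  edges <- matrix(0L, nrow = 2 * n_int, ncol = 2)
  lens <- numeric(2 * n_int)
  r <- 0L
  for (m in merges) {
    for (ch in m[2:3]) {
      r <- r + 1L
      edges[r, ] <- c(newid[m[1]], newid[ch])
      lens[r] <- node_age[m[1]] - if (ch <= N) 0 else node_age[ch]
    }
  }
  tr <- list(edge = edges, edge.length = lens, tip.label = tip_labels,
             Nnode = n_int)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Evolve sequences along a gene tree under the Jukes-Cantor model
#'
#' The root sequence is uniform over the four nucleotides; along each branch
#' of length `d` (expected mutations per site) every site changes with
#' probability `3/4 (1 - exp(-4 d / 3))`, uniformly to one of the other
#' three bases — the Jukes-Cantor transition probabilities.
#'
#' @param tree An [ape::phylo] gene tree with branch lengths in expected
#'   mutations per site.
#' @param n Number of sites.
#' @return A character matrix (`tips x n`) of `A`/`C`/`G`/`T`, rownames the
#'   tip labels.
#' @export
evolve_sequences_jc <- function(tree, n) {
  n <- check_count(n, "n")
  stopifnot(inherits(tree, "phylo"))
  tree <- ape::reorder.phylo(tree, "cladewise")
  N <- length(tree$tip.label)
  n_nodes <- N + tree$Nnode
  seqs <- matrix(0L, nrow = n_nodes, ncol = n)
  root <- N + 1L
  seqs[root, ] <- sample.int(4L, n, replace = TRUE)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    d <- tree$edge.length[e]
    p_change <- 0.75 * (-expm1(-4 * d / 3))
    s <- seqs[par, ]
    hit <- runif(n) < p_change
    if (any(hit)) {
      # uniform over the three other bases
      s[hit] <- ((s[hit] - 1L + sample.int(3L, sum(hit), replace = TRUE)) %% 4L) + 1L
    }
    seqs[ch, ] <- s
  }
  out <- matrix(c("A", "C", "G", "T")[seqs[seq_len(N), , drop = FALSE]],
                nrow = N)
  rownames(out) <- tree$tip.label
  out
}

#' Count pairwise sequence differences
#'
#' @param alignment Character matrix of aligned sequences (rows = sequences)
#'   or a named list of character vectors.
#' @param pair Length-2 vector of row names or indices.
#' @return A one-row tibble with columns `x` (differences) and `n` (sites).
#' @examples
#' aln <- rbind(a = c("A", "A", "A", "A"), b = c("A", "A", "A", "T"))
#' pairwise_diff_counts(aln, c("a", "b"))
#' @export
pairwise_diff_counts <- function(alignment,
                                 pair = if (is.matrix(alignment))
                                   rownames(alignment)[1:2]
                                 else names(alignment)[1:2]) {
  if (is.list(alignment)) {
    s1 <- alignment[[pair[1]]]
    s2 <- alignment[[pair[2]]]
  } else {
    s1 <- alignment[pair[1], ]
    s2 <- alignment[pair[2], ]
  }
  if (length(s1) != length(s2)) abort("sequences have different lengths")
  tibble(x = sum(s1 != s2), n = length(s1))
}

#' Simulate a multilocus dataset under a scenario
#'
#' Draws `L` independent gene trees on the scenario's network (per-locus
#' seeded substreams, so results are byte-identical under a fixed seed and
#' extending `L` does not reshuffle earlier loci), evolves Jukes-Cantor
#' sequences along each, and returns either the alignments or the pairwise
#' difference counts between the first sequences of a designated species
#' pair.
#'
#' @param scenario A [preset_scenario()] or `scenario_spec`-like list with
#'   elements `network` (or `params`), `L`, `S`, `n`.
#' @param seed Integer seed.
#' @param output `"alignments"` for the full per-locus alignments,
#'   `"counts"` for per-locus `(x, n)` pairs.
#' @param pair Species pair for `output = "counts"` (defaults to the first
#'   two sampled species).
#' @return An object of class `multilocus_dataset`: list with `loci` (list
#'   of alignments, or a tibble `locus`/`x`/`n`), `scenario`, `seed`.
#' @examples
#' sc <- preset_scenario("fig1-im", L = 5, S = 1, n = 100)
#' sim <- simulate_dataset(sc, seed = 1)
#' @export
simulate_dataset <- function(scenario, seed,
                             output = c("alignments", "counts"),
                             pair = NULL) {
  output <- match.arg(output)
  net <- scenario$network
  if (is.null(net)) net <- as_species_network(scenario$params)
  samples <- net$samples
  samples[] <- scenario$S
  L <- check_count(scenario$L, "L")
  n <- check_count(scenario$n, "n")
  species <- names(samples)
  if (is.null(pair)) pair <- head(species, 2)
  loci <- vector("list", L)
  for (l in seq_len(L)) {
    set.seed(mix_seed(seed, l))
    tr <- simulate_gene_tree(net, samples = samples)
    aln <- evolve_sequences_jc(tr, n)
    loci[[l]] <- aln
  }
  if (output == "counts") {
    counts <- dplyr::bind_rows(lapply(seq_len(L), function(l) {
      pairwise_diff_counts(loci[[l]], paste0(pair, "_1"))
    }))
    counts <- dplyr::mutate(counts, locus = dplyr::row_number(),
                            .before = 1)
    loci <- counts
  }
  structure(list(loci = loci, scenario = scenario, seed = seed,
                 output = output),
            class = "multilocus_dataset")
}

#' Fast simulation of per-locus difference counts for two-species models
#'
#' For one sequence per species, the observable per locus is the pair
#' `(x, n)`; conditional on the coalescent time `t` the count is binomial
#' with the Jukes-Cantor mismatch probability, so the full
#' sequence-evolution step can be collapsed: draw `t` from the exact
#' process sampler, then `x ~ Binomial(n, p(t))`. This is the generator used
#' for large-`L` likelihood studies.
#'
#' @param params Two-species model parameters.
#' @param L Number of loci.
#' @param n Sites per locus.
#' @param seed Optional integer seed.
#' @return A tibble with columns `locus`, `x`, `n`.
#' @export
simulate_locus_counts <- function(params, L, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- check_count(n, "n")
  t <- simulate_coal_times(params, L)
  tibble(locus = seq_len(L), x = rbinom(L, n, jc_mismatch_prob(t)), n = n)
}

#' @export
print.multilocus_dataset <- function(x, ...) {
  cat(sprintf("<multilocus_dataset: %d loci (%s), seed %s>\n",
              if (is.data.frame(x$loci)) nrow(x$loci) else length(x$loci),
              x$output, format(x$seed)))
  invisible(x)
}
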