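#' Named simulation scenarios
#'
#' Returns a fully populated scenario: the generating model (two-species
#' parameter set or multi-species network), the data dimensions (`L` loci,
#' `S` sequences per species, `n` sites) and the replicate count used in the
#' corresponding simulation study. All times and population sizes are in
#' expected mutations per site, with the two stock population sizes
#' `theta0 = 0.002` (thin branches) and `theta1 = 0.01` (thick branches).
#'
#' Available presets:
#' \describe{
#'   \item{`fig1-im`}{Two species, isolation with migration: `tauR = theta0 =
#'     0.002`, gene flow A to B over `(0, tauR)` at `M = 0.2`.}
#'   \item{`fig1-iim`}{Isolation with initial migration: `tauR = 2 theta0 =
#'     0.004`, gene flow over `(tauT, tauR)` with `tauT = theta0 = 0.002`.}
#'   \item{`fig1-sc`}{Secondary contact: gene flow over `(0, tauT)` with
#'     `tauT = 0.002`; `tauR = 0.004` (the interval of gene flow has length
#'     `theta0` in all three two-species presets; `tauR` for this preset is a
#'     documented package assumption chosen to match that geometry).}
#'   \item{`fig4-A`, `fig4-B`}{Four-species introgression models
#'     `(((B,C)T, A)S, D)R` with `tauR = 0.008`, `tauS = 0.006`, hybridisation
#'     A to B (A) or A to the ancestor of B and C (B) at `tauX = tauY = 0.003`
#'     with `phi = 0.2`; `tauT = 0.004` (A) or `0.002` (B).}
#'   \item{`fig4-C`, `fig4-D`}{Continuous-migration counterparts of A and B:
#'     A to B over `(0, 0.004)` (C), A to the BC ancestor over
#'     `(0.002, 0.006)` (D), at `M = 0.1`.}
#'   \item{`fig6-iim3`}{Three-species isolation-with-initial-migration
#'     `((A,B)S, C)R`, `tauR = 0.008`, `tauS = 0.006`, gene flow A to B over
#'     `(0.002, 0.006)` at `M = 0.1`.}
#'   \item{`fig7-ghost-intro`}{Ghost-donor introgression: the donor lineage
#'     splits from A at `tauX = 0.003` and is unsampled; it donates into B at
#'     `tauY = 0.002` with `phi = 0.2`. The topology placing C as outgroup
#'     and the ghost attachment points are a documented package assumption.}
#'   \item{`fig8-ghost-mig`}{Two-step ghost migration: an unsampled lineage
#'     SU receives migrants from C over `(0.002, 0.006)` and passes them to B
#'     over `(0.002, 0.004)`, both at `M = 0.2`.}
#' }
#'
#' @param name Preset name (see above).
#' @param L,S,n,replicates Optional overrides of the preset data dimensions.
#' @return A `scenario_spec` object: a list with elements `name`, `params`
#'   (two-species presets), `network`, `L`, `S`, `n`, `replicates`.
#' @examples
#' preset_scenario("fig1-iim")
#' @export
preset_scenario <- function(name, L = NULL, S = NULL, n = NULL,
                            replicates = NULL) {
  builders <- list(
    "fig1-im" = preset_fig1("im"),
    "fig1-iim" = preset_fig1("iim"),
    "fig1-sc" = preset_fig1("sc"),
    "fig4-A" = preset_fig4("A"),
    "fig4-B" = preset_fig4("B"),
    "fig4-C" = preset_fig4("C"),
    "fig4-D" = preset_fig4("D"),
    "fig6-iim3" = preset_fig6(),
    "fig7-ghost-intro" = preset_fig7(),
    "fig8-ghost-mig" = preset_fig8())
  if (!is.character(name) || length(name) != 1L || !name %in% names(builders)) {
    abort(paste0("unknown preset '", paste(name, collapse = ","),
                 "'; available presets: ",
                 paste(names(builders), collapse = ", ")))
  }
  sc <- builders[[name]]
  sc$name <- name
  if (!is.null(L)) sc$L <- check_count(L, "L")
  if (!is.null(S)) sc$S <- check_count(S, "S")
  if (!is.null(n)) sc$n <- check_count(n, "n")
  if (!is.null(replicates)) sc$replicates <- check_count(replicates, "replicates")
  structure(sc, class = "scenario_spec")
}

theta0 <- 0.002
theta1 <- 0.01

preset_fig1 <- function(variant) {
  tauR <- switch(variant, im = theta0, iim = 2 * theta0, sc = 2 * theta0)
  tauT <- switch(variant, im = 0, iim = theta0, sc = theta0)
  p <- mscm_params(variant, tauR = tauR, tauT = tauT,
                   thetaA = theta0, thetaB = theta1,
                   thetaR = theta1, thetaT = theta1, M = 0.2)
  net <- as_species_network(p)
  net$samples <- c(A = 4L, B = 4L)
  list(params = p, network = net, L = 4000L, S = 4L, n = 1000L,
       replicates = 30L)
}

# the MSci model used to analyse fig1-type data; theta assignments follow the
# thin/thick convention (donor segment S thin, root thick)
fig1_msci_truth <- function(gen) {
  msci_params(tauR = gen$tauR, tauS = gen$tauT, thetaR = gen$thetaR,
              thetaS = theta0, phi = 0,
              thetaA = theta0, thetaB = theta1, thetaH = theta1)
}

fig4_nodes <- function(tauT, hybrids) {
  # (((B,C)T, A)S, D)R  with degree-1 hybrid-timing nodes from `hybrids`
  base <- tibble(
    label = c("R", "S", "T", "A", "B", "C", "D"),
    parent = c(NA, "R", "S", "S", "T", "T", "R"),
    age = c(4 * theta0, 3 * theta0, tauT, 0, 0, 0, 0),
    theta = c(theta1, theta1, theta1, theta0, theta1, theta0, theta0))
  for (h in hybrids) {
    base$parent[base$label == h$child] <- h$label
    base <- rbind(base, tibble(label = h$label, parent = h$parent,
                               age = h$age, theta = h$theta))
  }
  base
}

preset_fig4 <- function(which) {
  tauXY <- 1.5 * theta0
  net <- switch(
    which,
    A = {
      nodes <- fig4_nodes(tauT = 2 * theta0, hybrids = list(
        list(label = "X", child = "A", parent = "S", age = tauXY, theta = theta0),
        list(label = "Y", child = "B", parent = "T", age = tauXY, theta = theta1)))
      species_network(
        nodes,
        events = tibble(time = tauXY, recipient = "B", donor = "X", phi = 0.2),
        samples = c(A = 4L, B = 4L, C = 4L, D = 4L))
    },
    B = {
      nodes <- fig4_nodes(tauT = theta0, hybrids = list(
        list(label = "X", child = "A", parent = "S", age = tauXY, theta = theta0),
        list(label = "Y", child = "T", parent = "S", age = tauXY, theta = theta1)))
      species_network(
        nodes,
        events = tibble(time = tauXY, recipient = "T", donor = "X", phi = 0.2),
        samples = c(A = 4L, B = 4L, C = 4L, D = 4L))
    },
    C = species_network(
      fig4_nodes(tauT = 2 * theta0, hybrids = list()),
      bands = tibble(donor = "A", recipient = "B", M = 0.1,
                     t_start = 0, t_end = 2 * theta0),
      samples = c(A = 4L, B = 4L, C = 4L, D = 4L)),
    D = species_network(
      fig4_nodes(tauT = theta0, hybrids = list()),
      bands = tibble(donor = "A", recipient = "T", M = 0.1,
                     t_start = theta0, t_end = 3 * theta0),
      samples = c(A = 4L, B = 4L, C = 4L, D = 4L)))
  list(params = NULL, network = net, L = 4000L, S = 4L, n = 500L,
       replicates = 100L)
}

preset_fig6 <- function() {
  nodes <- tibble(
    label = c("R", "S", "A", "B", "C"),
    parent = c(NA, "R", "S", "S", "R"),
    age = c(4 * theta0, 3 * theta0, 0, 0, 0),
    theta = c(theta1, theta1, theta0, theta1, theta0))
  net <- species_network(
    nodes,
    bands = tibble(donor = "A", recipient = "B", M = 0.1,
                   t_start = theta0, t_end = 3 * theta0),
    samples = c(A = 4L, B = 4L, C = 4L))
  list(params = NULL, network = net, L = 4000L, S = 4L, n = 500L,
       replicates = 100L)
}

preset_fig7 <- function() {
  # ghost donor lineage U splits from A at tauX and donates into B at tauY;
  # V is the unsampled sister of B below T
  nodes <- tibble(
    label = c("R", "S", "X", "T", "Y", "A", "U", "B", "V", "C"),
    parent = c(NA, "R", "S", "S", "T", "X", "X", "Y", "T", "R"),
    age = c(4 * theta0, 3 * theta0, 1.5 * theta0, 2 * theta0, theta0,
            0, 0, 0, 0, 0),
    theta = c(theta1, theta1, theta0, theta1, theta1,
              theta0, theta0, theta1, theta0, theta0))
  net <- species_network(
    nodes,
    events = tibble(time = theta0, recipient = "B", donor = "U", phi = 0.2),
    samples = c(A = 4L, B = 4L, C = 4L))
  list(params = NULL, network = net, L = 4000L, S = 4L, n = 500L,
       replicates = 100L)
}

preset_fig8 <- function() {
  nodes <- tibble(
    label = c("R", "S", "T", "U", "A", "B", "C", "V", "W"),
    parent = c(NA, "R", "S", "S", "T", "T", "R", "U", "U"),
    age = c(4 * theta0, 3 * theta0, 2 * theta0, theta0, 0, 0, 0, 0, 0),
    theta = c(theta1, theta0, theta0, theta1, theta0, theta1, theta0,
              theta0, theta0))
  net <- species_network(
    nodes,
    bands = tibble(donor = c("C", "U"), recipient = c("U", "B"),
                   M = c(0.2, 0.2),
                   t_start = c(theta0, theta0),
                   t_end = c(3 * theta0, 2 * theta0)),
    samples = c(A = 4L, B = 4L, C = 4L))
  list(params = NULL, network = net, L = 4000L, S = 4L, n = 500L,
       replicates = 100L)
}

#' The migration-rate grid of the two-species study
#'
#' @return Numeric vector of the 15 migration rates (migrants per generation)
#'   swept in the two-species simulations.
#' @export
migration_rate_grid <- function() {
  c(0.01, 0.02, 0.03, 0.04, 0.05, 0.07, 0.1, 0.2, 0.3, 0.4, 0.5, 0.7,
    1.0, 1.5, 2.0)
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec: %s>\n", x$name))
  cat(sprintf("  L = %d loci, S = %d seqs/species, n = %d sites, %d replicates\n",
              x$L, x$S, x$n, x$replicates))
  if (!is.null(x$params)) print(x$params)
  if (!is.null(x$network)) print(x$network)
  invisible(x)
}
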