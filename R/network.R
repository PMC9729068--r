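#' Species network with migration bands and introgression nodes
#'
#' A species tree (possibly with degree-1 "timing" nodes marking hybridisation
#' points or population-size changes along a branch) decorated with continuous
#' migration bands and episodic introgression events. This is the input to the
#' structured-coalescent simulator [simulate_gene_tree()].
#'
#' Each branch of the tree is named after its daughter node, so the branch
#' above node `X` spans the ages `(age(X), age(parent(X)))` and has population
#' size `theta(X)`. The root branch extends to infinity.
#'
#' @param nodes A data frame with columns `label`, `parent` (label of the
#'   parent node, `NA` for the root), `age` (expected mutations per site,
#'   0 = present) and `theta` (population size parameter of the branch above
#'   the node).
#' @param bands Optional data frame of continuous migration bands with columns
#'   `donor`, `recipient` (branch labels), `M` (migrants per generation) and
#'   `t_start < t_end` (active time interval). Backwards in time, each lineage
#'   in the recipient branch jumps into the donor branch at rate
#'   `w = 4 M / theta_recipient` while the band is active.
#' @param events Optional data frame of introgression events with columns
#'   `time`, `recipient`, `donor` and `phi`: at `time`, every lineage in the
#'   recipient branch moves into the donor branch independently with
#'   probability `phi`. The donor branch must span `time`.
#' @param samples Named integer vector of sequences sampled per tip species;
#'   tips absent from the vector (ghost species) contribute no samples.
#' @return An object of class `species_network`.
#' @seealso [parse_species_network()], [write_species_network()],
#'   [validate_params()]
#' @examples
#' nodes <- data.frame(
#'   label = c("R", "A", "B"), parent = c(NA, "R", "R"),
#'   age = c(0.002, 0, 0), theta = c(0.01, 0.002, 0.01))
#' net <- species_network(nodes, samples = c(A = 1, B = 1))
#' @export
species_network <- function(nodes, bands = NULL, events = NULL,
                            samples = NULL) {
  nodes <- as_tibble(nodes)
  stopifnot(all(c("label", "parent", "age", "theta") %in% names(nodes)))
  nodes$label <- as.character(nodes$label)
  nodes$parent <- as.character(nodes$parent)
  empty_bands <- tibble(donor = character(), recipient = character(),
                        M = double(), t_start = double(), t_end = double())
  empty_events <- tibble(time = double(), recipient = character(),
                         donor = character(), phi = double())
  bands <- if (is.null(bands)) empty_bands else as_tibble(bands)
  events <- if (is.null(events)) empty_events else as_tibble(events)
  if (is.null(samples)) samples <- integer()
  net <- structure(
    list(nodes = nodes, bands = bands, events = events,
         samples = samples),
    class = "species_network")
  net
}

net_tips <- function(net) {
  setdiff(net$nodes$label, net$nodes$parent[!is.na(net$nodes$parent)])
}

net_root <- function(net) net$nodes$label[is.na(net$nodes$parent)]

node_age <- function(net, label) {
  net$nodes$age[match(label, net$nodes$label)]
}

# time interval spanned by the branch named after `label`
branch_interval <- function(net, label) {
  i <- match(label, net$nodes$label)
  parent <- net$nodes$parent[i]
  top <- if (is.na(parent)) Inf else net$nodes$age[match(parent, net$nodes$label)]
  c(net$nodes$age[i], top)
}

#' @export
validate_params.species_network <- function(x) {
  v <- no_violations()
  n <- x$nodes
  if (sum(is.na(n$parent)) != 1L) {
    v <- rbind(v, violation("nodes", "network must have exactly one root"))
  }
  if (anyDuplicated(n$label)) {
    v <- rbind(v, violation("nodes", "node labels must be unique"))
  }
  bad_parent <- setdiff(n$parent[!is.na(n$parent)], n$label)
  if (length(bad_parent)) {
    v <- rbind(v, violation("nodes", paste0("unknown parent label(s): ",
                                            paste(bad_parent, collapse = ", "))))
  }
  if (any(n$theta <= 0)) {
    v <- rbind(v, violation("theta", "all theta must be > 0"))
  }
  for (i in seq_len(nrow(n))) {
    p <- n$parent[i]
    if (!is.na(p) && p %in% n$label) {
      if (n$age[i] >= n$age[match(p, n$label)]) {
        v <- rbind(v, violation(
          n$label[i],
          sprintf("age (%g) must be strictly less than parent %s age (%g)",
                  n$age[i], p, n$age[match(p, n$label)])))
      }
    }
  }
  if (nrow(v)) return(v)  # interval checks need a well-formed tree
  for (i in seq_len(nrow(x$bands))) {
    b <- x$bands[i, ]
    if (!(b$donor %in% n$label) || !(b$recipient %in% n$label)) {
      v <- rbind(v, violation("bands", "band references unknown branch"))
      next
    }
    if (b$t_start >= b$t_end || b$M < 0) {
      v <- rbind(v, violation("bands", "band needs t_start < t_end and M >= 0"))
    }
    for (side in c("donor", "recipient")) {
      iv <- branch_interval(x, b[[side]])
      if (b$t_end <= iv[1] || b$t_start >= iv[2]) {
        v <- rbind(v, violation(
          "bands", sprintf("band interval (%g, %g) does not overlap %s branch %s",
                           b$t_start, b$t_end, side, b[[side]])))
      }
    }
  }
  for (i in seq_len(nrow(x$events))) {
    e <- x$events[i, ]
    if (e$phi < 0 || e$phi > 1) {
      v <- rbind(v, violation("events", "phi must lie in [0, 1]"))
    }
    if (!(e$recipient %in% n$label) || !(e$donor %in% n$label)) {
      v <- rbind(v, violation("events", "event references unknown branch"))
      next
    }
    riv <- branch_interval(x, e$recipient)
    div <- branch_interval(x, e$donor)
    if (e$time < riv[1] || e$time > riv[2]) {
      v <- rbind(v, violation(
        "events", sprintf("event time %g outside recipient branch %s",
                          e$time, e$recipient)))
    }
    if (e$time < div[1] || e$time > div[2]) {
      v <- rbind(v, violation(
        "events", sprintf("event time %g outside donor branch %s",
                          e$time, e$donor)))
    }
  }
  bad_sample <- setdiff(names(x$samples), net_tips(x))
  if (length(bad_sample)) {
    v <- rbind(v, violation("samples", paste0("samples assigned to non-tip: ",
                                              paste(bad_sample, collapse = ", "))))
  }
  v
}

#' @export
print.species_network <- function(x, ...) {
  cat(sprintf("<species_network: %d nodes, %d tips, %d bands, %d events>\n",
              nrow(x$nodes), length(net_tips(x)), nrow(x$bands),
              nrow(x$events)))
  invisible(x)
}

#' Convert two-species parameter sets to a species network
#'
#' Builds the explicit network representation used by the simulator from an
#' [mscm_params()] or [msci_params()] object. Migration variants become a
#' single A-to-B band over the variant's gene-flow interval; the MSci model
#' becomes a tree with degree-1 nodes S (donor segment on the A lineage) and
#' H (recipient segment on the B lineage) at the introgression time.
#'
#' @param params An `mscm_params` or `msci_params` object.
#' @param theta_tip Population size used for the tips of the MSci network when
#'   the non-identifiable `thetaA`/`thetaB`/`thetaH` are `NA` (they never see
#'   a coalescent event with one sequence per species).
#' @return A [species_network()].
#' @export
as_species_network <- function(params, theta_tip = 0.002) {
  if (inherits(params, "mscm_params")) {
    stop_if_invalid(params)
    nodes <- tibble(
      label = c("R", "A", "B"),
      parent = c(NA, "R", "R"),
      age = c(params$tauR, 0, 0),
      theta = c(params$thetaR, params$thetaA, params$thetaB))
    interval <- switch(params$variant,
      im  = c(0, params$tauR),
      iim = c(params$tauT, params$tauR),
      sc  = c(0, params$tauT))
    bands <- tibble(donor = "A", recipient = "B", M = params$M,
                    t_start = interval[1], t_end = interval[2])
    return(species_network(nodes, bands = bands, samples = c(A = 1L, B = 1L)))
  }
  if (inherits(params, "msci_params")) {
    stop_if_invalid(params)
    thA <- if (is.na(params$thetaA)) theta_tip else params$thetaA
    thB <- if (is.na(params$thetaB)) theta_tip else params$thetaB
    thH <- if (is.na(params$thetaH)) theta_tip else params$thetaH
    nodes <- tibble(
      label = c("R", "S", "H", "A", "B"),
      parent = c(NA, "R", "R", "S", "H"),
      age = c(params$tauR, params$tauS, params$tauS, 0, 0),
      theta = c(params$thetaR, params$thetaS, thH, thA, thB))
    events <- tibble(time = params$tauS, recipient = "B", donor = "S",
                     phi = params$phi)
    return(species_network(nodes, events = events,
                           samples = c(A = 1L, B = 1L)))
  }
  abort("`params` must be an mscm_params or msci_params object.")
}
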