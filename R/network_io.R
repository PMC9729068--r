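#' Read and write species networks as annotated extended Newick
#'
#' The serialisation format is a text block whose first line is an extended
#' Newick string and whose remaining lines (if any) describe migration bands
#' and tip sample counts:
#'
#' ```
#' ((A[&age=0,theta=0.002])S[&age=0.002,theta=0.002], ...)R[&age=0.004,theta=0.01];
#' band A B 0.2 0 0.002
#' samples A=1 B=1
#' ```
#'
#' Every node carries an `[&age=...,theta=...]` annotation; degree-1 nodes
#' (timing/hybridisation points along a branch) are written as
#' `(child)label[...]`. Introgression events use hybrid tags in the style of
#' network Newick dialects: the hybrid node appears twice under the same
#' `#H<k>` tag, once in its tree position with its child subtree, and once as
#' a childless occurrence attached to the donor node, annotated with the
#' introgression probability `phi`. The childless occurrence's parent names
#' the donor branch that jumping lineages enter at the hybrid node's age.
#'
#' `write_species_network()` requires each event's recipient branch to be
#' capped by a degree-1 node at the event time (all shipped presets are built
#' this way); `parse_species_network()` inverts it losslessly.
#'
#' @param text A single string (or character vector of lines) in the format
#'   above.
#' @param net A [species_network()].
#' @return `parse_species_network()` returns a [species_network()];
#'   `write_species_network()` returns a single string.
#' @examples
#' net <- as_species_network(
#'   msci_params(0.004, 0.002, 0.01, 0.002, phi = 0.2))
#' txt <- write_species_network(net)
#' identical_net <- parse_species_network(txt)
#' @name network_io
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_num <- function(x) sprintf("%.17g", x)

#' @rdname network_io
#' @export
write_species_network <- function(net) {
  stopifnot(inherits(net, "species_network"))
  v <- validate_params(net)
  if (nrow(v)) abort("cannot serialise an invalid network; run validate_params()")
  nodes <- net$nodes
  events <- net$events
  # events are keyed by the degree-1 node capping the recipient branch
  hyb <- list()
  if (nrow(events)) {
    for (k in seq_len(nrow(events))) {
      e <- events[k, ]
      cap <- nodes$parent[match(e$recipient, nodes$label)]
      if (is.na(cap) || node_age(net, cap) != e$time ||
          sum(nodes$parent == cap, na.rm = TRUE) != 1L) {
        abort(paste0("event ", k, ": recipient branch ", e$recipient,
                     " must be capped by a degree-1 node at the event time ",
                     "for serialisation"))
      }
      hyb[[cap]] <- list(tag = paste0("#H", k), donor = e$donor, phi = e$phi)
    }
  }
  children <- split(nodes$label, factor(nodes$parent, levels = nodes$label))
  ann <- function(lab, extra = NULL) {
    i <- match(lab, nodes$label)
    parts <- c(sprintf("age=%s", fmt_num(nodes$age[i])),
               sprintf("theta=%s", fmt_num(nodes$theta[i])), extra)
    sprintf("[&%s]", paste(parts, collapse = ","))
  }
  ser <- function(lab) {
    kid_strs <- vapply(children[[lab]], ser, "")
    # donor-side childless occurrences attached below this node
    for (cap in names(hyb)) {
      if (hyb[[cap]]$donor == lab) {
        kid_strs <- c(kid_strs,
                      paste0(cap, hyb[[cap]]$tag,
                             sprintf("[&age=%s,phi=%s]",
                                     fmt_num(node_age(net, cap)),
                                     fmt_num(hyb[[cap]]$phi))))
      }
    }
    kid_part <- if (length(kid_strs)) {
      paste0("(", paste(kid_strs, collapse = ","), ")")
    } else ""
    tag <- if (!is.null(hyb[[lab]])) hyb[[lab]]$tag else ""
    paste0(kid_part, lab, tag, ann(lab))
  }
  lines <- paste0(ser(net_root(net)), ";")
  if (nrow(net$bands)) {
    for (i in seq_len(nrow(net$bands))) {
      b <- net$bands[i, ]
      lines <- c(lines, sprintf("band %s %s %s %s %s", b$donor, b$recipient,
                                fmt_num(b$M), fmt_num(b$t_start),
                                fmt_num(b$t_end)))
    }
  }
  if (length(net$samples)) {
    lines <- c(lines, paste("samples",
                            paste(sprintf("%s=%d", names(net$samples),
                                          as.integer(net$samples)),
                                  collapse = " ")))
  }
  paste(lines, collapse = "\n")
}

#' @rdname network_io
#' @export
parse_species_network <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort("empty network text")
  newick <- lines[1]
  rest <- lines[-1]

  s <- gsub("[[:space:]]", "", newick)
  pos <- 1L
  n_s <- nchar(s)
  peek <- function() if (pos <= n_s) substr(s, pos, pos) else ""
  fail <- function(msg) abort(sprintf("network parse error at position %d: %s",
                                      pos, msg))

  read_label <- function() {
    start <- pos
    while (pos <= n_s && !substr(s, pos, pos) %in% c("(", ")", ",", ";", "[")) {
      pos <<- pos + 1L
    }
    substr(s, start, pos - 1L)
  }
  read_annotation <- function() {
    if (peek() != "[") return(list())
    close <- regexpr("]", substr(s, pos, n_s), fixed = TRUE)
    if (close < 0) fail("unterminated annotation")
    body <- substr(s, pos + 2L, pos + close - 2L)  # strip "[&" and "]"
    pos <<- pos + close
    kv <- strsplit(strsplit(body, ",")[[1]], "=")
    vals <- lapply(kv, function(p) suppressWarnings(as.numeric(p[2])))
    names(vals) <- vapply(kv, `[[`, "", 1)
    if (anyNA(unlist(vals))) fail("non-numeric annotation value")
    vals
  }

  # occurrence records: label, tag, parent occurrence id, has_children, ann
  occ <- list()
  parse_node <- function(parent_id) {
    my_id <- NA_integer_
    kid_ids <- integer()
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        kid_ids <- c(kid_ids, parse_node(parent_id = NA))
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        fail("expected ',' or ')'")
      }
    }
    label_raw <- read_label()
    if (!nzchar(label_raw)) fail("every node needs a label")
    ann <- read_annotation()
    tag <- NA_character_
    label <- label_raw
    if (grepl("#", label_raw, fixed = TRUE)) {
      parts <- strsplit(label_raw, "#", fixed = TRUE)[[1]]
      if (length(parts) != 2L || !nzchar(parts[1]) || !nzchar(parts[2])) {
        fail(paste0("malformed hybrid label: ", label_raw))
      }
      label <- parts[1]; tag <- parts[2]
    }
    my_id <- length(occ) + 1L
    occ[[my_id]] <<- list(label = label, tag = tag,
                          parent = NA_integer_,
                          has_children = length(kid_ids) > 0L,
                          age = ann$age, theta = ann$theta, phi = ann$phi)
    for (k in kid_ids) occ[[k]]$parent <<- my_id
    my_id
  }
  root_id <- parse_node(parent_id = NA)
  if (peek() != ";") fail("expected ';' at end of tree")

  labs <- vapply(occ, `[[`, "", "label")
  tags <- vapply(occ, function(r) r$tag %||% NA_character_, "")
  haskid <- vapply(occ, `[[`, TRUE, "has_children")

  donor_ref <- rep(FALSE, length(occ))
  for (tg in unique(tags[!is.na(tags)])) {
    ids <- which(!is.na(tags) & tags == tg)
    if (length(ids) != 2L) {
      abort(sprintf("hybrid tag #%s must appear exactly twice (found %d)",
                    tg, length(ids)))
    }
    if (sum(haskid[ids]) != 1L) {
      abort(sprintf(
        "hybrid tag #%s needs one tree occurrence (with a child) and one donor reference",
        tg))
    }
    if (labs[ids[1]] != labs[ids[2]]) {
      abort(sprintf("hybrid tag #%s used with two different labels", tg))
    }
    donor_ref[ids[!haskid[ids]]] <- TRUE
  }

  keep <- which(!donor_ref)
  if (anyDuplicated(labs[keep])) {
    dup <- unique(labs[keep][duplicated(labs[keep])])
    abort(paste0("duplicate node label(s): ", paste(dup, collapse = ", ")))
  }
  ages <- vapply(occ[keep], function(r) r$age %||% NA_real_, 0)
  thetas <- vapply(occ[keep], function(r) r$theta %||% NA_real_, 0)
  if (anyNA(ages) || anyNA(thetas)) {
    miss <- labs[keep][is.na(ages) | is.na(thetas)]
    abort(paste0("node(s) missing age/theta annotation: ",
                 paste(miss, collapse = ", ")))
  }
  parent_lab <- vapply(occ[keep], function(r) {
    if (is.na(r$parent)) NA_character_ else labs[r$parent]
  }, "")
  nodes <- tibble(label = labs[keep], parent = parent_lab,
                  age = ages, theta = thetas)

  events <- NULL
  for (tg in unique(tags[!is.na(tags)])) {
    ids <- which(!is.na(tags) & tags == tg)
    tree_id <- ids[haskid[ids]]
    ref_id <- ids[!haskid[ids]]
    cap <- labs[tree_id]
    kids <- labs[vapply(occ, function(r) identical(r$parent, tree_id), TRUE)]
    if (length(kids) != 1L) {
      abort(sprintf("hybrid node %s must have exactly one child", cap))
    }
    phi <- occ[[ref_id]]$phi %||% occ[[tree_id]]$phi
    if (is.null(phi)) abort(sprintf("hybrid tag #%s missing phi annotation", tg))
    donor <- labs[occ[[ref_id]]$parent]
    events <- rbind(events, tibble(
      time = nodes$age[match(cap, nodes$label)],
      recipient = kids, donor = donor, phi = phi))
  }

  bands <- NULL
  samples <- integer()
  for (ln in rest) {
    toks <- strsplit(ln, "[[:space:]]+")[[1]]
    if (toks[1] == "band") {
      if (length(toks) != 6L) abort(paste0("malformed band line: ", ln))
      bands <- rbind(bands, tibble(
        donor = toks[2], recipient = toks[3], M = as.numeric(toks[4]),
        t_start = as.numeric(toks[5]), t_end = as.numeric(toks[6])))
    } else if (toks[1] == "samples") {
      kv <- strsplit(toks[-1], "=", fixed = TRUE)
      samples <- setNames(vapply(kv, function(p) as.integer(p[2]), 1L),
                          vapply(kv, `[[`, "", 1))
    } else {
      abort(paste0("unrecognised line: ", ln))
    }
  }

  net <- species_network(nodes, bands = bands, events = events,
                         samples = samples)
  v <- validate_params(net)
  if (nrow(v)) {
    abort(paste0("parsed network is invalid: ",
                 paste(sprintf("%s (%s)", v$field, v$rule), collapse = "; ")))
  }
  net
}
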