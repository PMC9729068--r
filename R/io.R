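#' Write and read multilocus data files
#'
#' `write_phylip()` writes a multilocus alignment dataset in the sequential
#' multilocus PHYLIP dialect used by coalescent samplers (one `ns ls` header
#' per locus, blank-line separated). `write_fasta()` writes one FASTA block
#' per locus with `>species_seq|locus` headers. `write_counts_tsv()` /
#' `read_counts_tsv()` round-trip per-locus difference-count tables as TSV
#' with header `locus x n` (reading also accepts plain `x n` tables).
#' `write_gene_trees()` writes one Newick string per line with branch
#' lengths in expected mutations per site.
#'
#' @param dataset A `multilocus_dataset` from [simulate_dataset()] (with
#'   `output = "alignments"`).
#' @param counts A data frame with columns `x`, `n` (and optionally
#'   `locus`).
#' @param trees A list of [ape::phylo] objects.
#' @param path Output file path.
#' @return The path, invisibly; `read_counts_tsv()` returns a tibble.
#' @name multilocus_io
NULL

#' @rdname multilocus_io
#' @export
write_phylip <- function(dataset, path) {
  stopifnot(inherits(dataset, "multilocus_dataset"),
            !is.data.frame(dataset$loci))
  con <- file(path, "w")
  on.exit(close(con))
  for (aln in dataset$loci) {
    writeLines(sprintf("%d %d", nrow(aln), ncol(aln)), con)
    writeLines(sprintf("%-12s  %s", rownames(aln),
                       apply(aln, 1, paste0, collapse = "")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname multilocus_io
#' @export
write_fasta <- function(dataset, path) {
  stopifnot(inherits(dataset, "multilocus_dataset"),
            !is.data.frame(dataset$loci))
  con <- file(path, "w")
  on.exit(close(con))
  for (l in seq_along(dataset$loci)) {
    aln <- dataset$loci[[l]]
    for (i in seq_len(nrow(aln))) {
      writeLines(c(sprintf(">%s|locus%d", rownames(aln)[i], l),
                   paste0(aln[i, ], collapse = "")), con)
    }
  }
  invisible(path)
}

#' @rdname multilocus_io
#' @export
write_counts_tsv <- function(counts, path) {
  stopifnot(all(c("x", "n") %in% names(counts)))
  if (!"locus" %in% names(counts)) {
    counts <- dplyr::mutate(counts, locus = dplyr::row_number(), .before = 1)
  }
  utils::write.table(counts[c("locus", "x", "n")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname multilocus_io
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("x", "n") %in% names(df))) {
    abort(sprintf("'%s' does not look like a counts table (need columns x, n)",
                  path))
  }
  as_tibble(df)
}

#' @rdname multilocus_io
#' @export
write_gene_trees <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  writeLines(vapply(trees, function(tr) ape::write.tree(tr), ""), path)
  invisible(path)
}
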