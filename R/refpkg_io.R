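#' Read and write FASTA sequence files
#'
#' Thin wrappers around Biostrings, returning/accepting plain named
#' character vectors so downstream motif and fragmentation functions can
#' stay string-based.
#'
#' @param path file path.
#' @param type `"AA"` or `"DNA"`.
#' @return `read_fasta()`: named character vector.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- if (type == "AA") Biostrings::readAAStringSet(path)
  else Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  invisible(path)
}

#' Write / read a reference package directory
#'
#' A reference package is a directory holding the reference tree with jplace
#' edge numbering (`tree.nwk`), the gene region definitions
#' (`regions.tsv`: `gene`, `role`, `tip`), and the reference amino-acid
#' sequences (`refs.faa`). Regions are re-derived from tip sets on read, so
#' the round trip revalidates monophyly and disjointness.
#'
#' @param refpkg a `nitro_refpkg` (see [simulate_refpkg()]).
#' @param dir directory to create/read.
#' @return `write_refpkg()`: `dir` invisibly. `read_refpkg()`: a
#'   `nitro_refpkg`.
#' @export
write_refpkg <- function(refpkg, dir) {
  stopifnot(inherits(refpkg, "nitro_refpkg"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(write_newick(refpkg$tree, edge_numbers = TRUE),
             file.path(dir, "tree.nwk"))
  tl <- tip_labels(refpkg$tree)
  rows <- purrr::map_dfr(names(refpkg$regions$nodes), function(g) {
    nodes <- refpkg$regions$nodes[[g]]
    labs <- refpkg$tree$label[nodes]
    tibble::tibble(gene = g, role = unname(refpkg$regions$roles[[g]]),
                   tip = labs[labs %in% tl])
  })
  utils::write.table(rows, file.path(dir, "regions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_fasta(refpkg$sequences, file.path(dir, "refs.faa"))
  invisible(dir)
}

#' @rdname write_refpkg
#' @export
read_refpkg <- function(dir) {
  tree <- parse_newick(paste(readLines(file.path(dir, "tree.nwk"), warn = FALSE),
                             collapse = ""))
  reg <- utils::read.table(file.path(dir, "regions.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  tip_sets <- split(reg$tip, reg$gene)
  roles <- vapply(split(reg$role, reg$gene), `[`, character(1), 1)
  regions <- label_regions(tree, tip_sets[names(roles)], roles = roles)
  sequences <- read_fasta(file.path(dir, "refs.faa"), type = "AA")
  structure(list(tree = tree, regions = regions, sequences = sequences,
                 classes = NULL, seed = NA_integer_),
            class = "nitro_refpkg")
}
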