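#' Read a jplace placement file
#'
#' Decodes jplace v3 (canonical) and v1 documents: the `tree` field with
#' `{N}` edge numbering, the `fields` array (honored in any order), and both
#' the `"n"` (names) and `"nm"` (name/multiplicity pairs) read-naming
#' conventions. Every placement edge must exist in the tree.
#'
#' @param x path to a `.jplace` file, or a jplace JSON string.
#' @param sample sample id to attach; defaults to the file base name.
#' @return a list with `tree` (a [nitro_tree]) and `placements`, a tibble of
#'   class `nitro_placements` with one row per read and placement:
#'   `name`, `multiplicity`, `edge` (jplace edge number),
#'   `like_weight_ratio`, `likelihood`.
#' @export
read_jplace <- function(x, sample = NULL) {
  if (length(x) == 1L && !grepl("{", x, fixed = TRUE) && file.exists(x)) {
    if (is.null(sample)) sample <- sub("\\.jplace$", "", basename(x))
    doc <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  } else {
    doc <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  }
  if (is.null(sample)) sample <- "sample"
  for (need in c("tree", "placements", "fields")) {
    if (is.null(doc[[need]])) stop("jplace document lacks '", need, "'", call. = FALSE)
  }
  tree <- parse_newick(doc$tree)
  fields <- unlist(doc$fields)
  known <- c("edge_num", "likelihood", "like_weight_ratio",
             "distal_length", "pendant_length", "post_prob",
             "marginal_like", "marginal_prob", "classification")
  if (!all(fields %in% known)) {
    stop("unknown jplace field(s): ",
         paste(setdiff(fields, known), collapse = ", "), call. = FALSE)
  }
  for (need in c("edge_num", "like_weight_ratio")) {
    if (!need %in% fields) stop("jplace 'fields' lacks '", need, "'", call. = FALSE)
  }
  i_edge <- match("edge_num", fields)
  i_lwr <- match("like_weight_ratio", fields)
  i_lik <- match("likelihood", fields)
  rows <- purrr::map_dfr(doc$placements, function(pl) {
    if (!is.null(pl$nm)) {
      names_mult <- purrr::map_dfr(pl$nm, function(nm) {
        tibble::tibble(name = as.character(nm[[1]]), multiplicity = as.numeric(nm[[2]]))
      })
    } else if (!is.null(pl$n)) {
      names_mult <- tibble::tibble(name = unlist(pl$n), multiplicity = 1)
    } else {
      stop("placement without 'n' or 'nm' name entry", call. = FALSE)
    }
    p <- purrr::map_dfr(pl$p, function(row) {
      tibble::tibble(
        edge = as.integer(row[[i_edge]]),
        like_weight_ratio = as.numeric(row[[i_lwr]]),
        likelihood = if (is.na(i_lik)) NA_real_ else as.numeric(row[[i_lik]])
      )
    })
    tidyr::crossing(names_mult, p)
  })
  if (nrow(rows) == 0L) {
    rows <- tibble::tibble(name = character(), multiplicity = numeric(),
                           edge = integer(), like_weight_ratio = numeric(),
                           likelihood = numeric())
  }
  if (nrow(rows) > 0L) {
    edge_node(tree, unique(rows$edge)) # errors on unknown edges
    bad <- rows |>
      dplyr::group_by(.data$name) |>
      dplyr::summarise(m = sum(.data$like_weight_ratio), .groups = "drop") |>
      dplyr::filter(.data$m > 1 + 1e-6)
    if (nrow(bad) > 0L) {
      stop("like_weight_ratio sums exceed 1 for read(s): ",
           paste(utils::head(bad$name, 5), collapse = ", "), call. = FALSE)
    }
  }
  placements <- structure(rows, sample = sample,
                          class = c("nitro_placements", class(rows)))
  list(tree = tree, placements = placements)
}

#' Write placements as a jplace v3 document
#'
#' @param tree a [nitro_tree].
#' @param placements a `nitro_placements` tibble (see [read_jplace()]).
#' @param path output file; when `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
write_jplace <- function(tree, placements, path = NULL) {
  by_read <- split(placements, placements$name)
  pl <- lapply(by_read, function(d) {
    list(
      p = lapply(seq_len(nrow(d)), function(i) {
        list(d$edge[i], d$like_weight_ratio[i],
             if (is.na(d$likelihood[i])) 0 else d$likelihood[i])
      }),
      nm = list(list(d$name[1], d$multiplicity[1]))
    )
  })
  doc <- list(
    version = 3,
    tree = write_newick(tree, edge_numbers = TRUE),
    fields = list("edge_num", "like_weight_ratio", "likelihood"),
    placements = unname(pl),
    metadata = list(invocation = "nitroplace")
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' Label monophyletic gene regions on a reference tree
#'
#' A region is the edge set of the minimal clade spanning a gene's reference
#' tips: all edges inside the clade plus the edge subtending it (the root
#' carries no edge and belongs to no region). Target regions must be pairwise
#' edge-disjoint; outgroup regions are carried along for reporting but do not
#' receive reads.
#'
#' @param tree a [nitro_tree].
#' @param tips named list, gene label -> character vector of tip labels.
#' @param roles named character, gene label -> `"target"` or `"outgroup"`;
#'   defaults to all `"target"`.
#' @return a `nitro_regions` object: list with `edges` (gene -> integer
#'   vector of jplace edge numbers), `roles`, and `genes` tibble.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' rg <- label_regions(tr, list(nrfA = c("A", "B"), outgroup = c("C", "D")),
#'                     roles = c(nrfA = "target", outgroup = "outgroup"))
#' @export
label_regions <- function(tree, tips, roles = NULL) {
  stopifnot(is.list(tips), length(tips) >= 1L, !is.null(names(tips)))
  if (is.null(roles)) roles <- stats::setNames(rep("target", length(tips)), names(tips))
  stopifnot(all(names(tips) %in% names(roles)), all(roles %in% c("target", "outgroup")))
  tl <- tip_labels(tree)
  tip_ids <- which(lengths(tree$children) == 0L)
  node_sets <- lapply(names(tips), function(g) {
    want <- tips[[g]]
    if (length(want) == 0L) stop("empty tip set for region '", g, "'", call. = FALSE)
    miss <- setdiff(want, tl)
    if (length(miss) > 0L) {
      stop("region '", g, "' names tips absent from the tree: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    nodes <- tip_ids[match(want, tl)]
    m <- mrca_node(tree, nodes)
    setdiff(clade_nodes(tree, m), tree$root) # edge per non-root node
  })
  names(node_sets) <- names(tips)
  targets <- names(tips)[roles[names(tips)] == "target"]
  if (length(targets) >= 2L) {
    for (i in seq_along(targets)[-1]) {
      for (j in seq_len(i - 1L)) {
        shared <- intersect(node_sets[[targets[i]]], node_sets[[targets[j]]])
        if (length(shared) > 0L) {
          stop("target regions '", targets[i], "' and '", targets[j],
               "' overlap on edges ",
               paste(tree$edge_num[shared], collapse = ", "), call. = FALSE)
        }
      }
    }
  }
  structure(
    list(
      edges = lapply(node_sets, function(v) sort(tree$edge_num[v])),
      nodes = node_sets,
      roles = roles[names(tips)],
      genes = tibble::tibble(gene = names(tips), role = unname(roles[names(tips)]),
                             n_edges = lengths(node_sets))
    ),
    class = "nitro_regions"
  )
}

#' @export
print.nitro_regions <- function(x, ...) {
  cat("<nitro_regions>\n")
  print(x$genes)
  invisible(x)
}
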