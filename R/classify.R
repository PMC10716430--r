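#' Accumulate a read's placement mass towards the root
#'
#' A short placed read usually receives several candidate placements, each
#' with a likelihood weight ratio (LWR). Walking from the tips towards the
#' root, the distal mass of an edge is the LWR attached to the edge itself
#' plus everything below it. The accumulated location of the read is the
#' edge *furthest from the root* whose distal mass reaches `threshold` times
#' the read's total mass: the smallest clade that confidently contains the
#' read.
#'
#' With `threshold > 0.5` the qualifying edges form a single root-ward
#' chain, so the most distal one is unique. If no single edge qualifies the
#' read accumulates to the (virtual) root and `NA` is returned.
#'
#' By default the threshold is relative to the read's realized total mass
#' `M` (reported LWRs need not sum to 1); set `relative = FALSE` to compare
#' against an absolute mass of 1.
#'
#' @param tree a [nitro_tree].
#' @param placements tibble/data frame with columns `edge` (jplace edge
#'   number) and `like_weight_ratio` for a single read.
#' @param threshold mass fraction in (0.5, 1].
#' @param relative threshold relative to realized total mass (default) or
#'   absolute.
#' @return the jplace edge number of the accumulated edge, or `NA_integer_`
#'   for the root sentinel.
#' @export
accumulate_read <- function(tree, placements, threshold = 0.95, relative = TRUE) {
  if (nrow(placements) == 0L) stop("read has no placements", call. = FALSE)
  if (threshold <= 0.5 || threshold > 1) {
    stop("threshold must be in (0.5, 1] so the accumulated edge is unique",
         call. = FALSE)
  }
  nodes <- edge_node(tree, placements$edge)
  mass <- numeric(tree$n_node)
  for (i in seq_along(nodes)) {
    mass[nodes[i]] <- mass[nodes[i]] + placements$like_weight_ratio[i]
  }
  M <- sum(placements$like_weight_ratio)
  target <- threshold * (if (relative) M else 1)
  acc <- mass
  for (v in tree$postorder) {
    for (ch in tree$children[[v]]) acc[v] <- acc[v] + acc[ch]
  }
  qual <- setdiff(which(acc >= target - 1e-12), tree$root)
  if (length(qual) == 0L) return(NA_integer_)
  tree$edge_num[qual[which.max(tree$depth[qual])]]
}

# per-target-region mass of one read (named numeric, gene -> mass)
region_masses <- function(tree, regions, placements) {
  nodes <- edge_node(tree, placements$edge)
  targets <- names(regions$nodes)[regions$roles == "target"]
  vapply(targets, function(g) {
    sum(placements$like_weight_ratio[nodes %in% regions$nodes[[g]]])
  }, numeric(1))
}

#' Assign a gene label from an accumulated edge
#'
#' An accumulated edge inside exactly one target gene region yields that
#' gene. An edge outside every target region (including the root sentinel)
#' is `dual_discarded` when at least two target regions each hold more than
#' `(1 - threshold) * M` of the read's mass — the minimal leak that could
#' have prevented confinement to a single gene — and `unassigned` otherwise.
#'
#' @param tree a [nitro_tree].
#' @param regions a `nitro_regions` (see [label_regions()]).
#' @param edge accumulated jplace edge number (`NA` for the root sentinel).
#' @param masses named numeric of per-target-region mass (gene -> mass).
#' @param total_mass the read's realized total mass `M`.
#' @param threshold the accumulation threshold used.
#' @return a label: a gene name, `"dual_discarded"`, or `"unassigned"`.
#' @export
assign_gene <- function(tree, regions, edge, masses, total_mass,
                        threshold = 0.95) {
  if (!is.na(edge)) {
    node <- edge_node(tree, edge)
    targets <- names(regions$nodes)[regions$roles == "target"]
    inside <- targets[vapply(targets, function(g) node %in% regions$nodes[[g]],
                             logical(1))]
    if (length(inside) == 1L) return(inside)
  }
  eps <- (1 - threshold) * total_mass
  if (sum(masses > eps + 1e-12) >= 2L) return("dual_discarded")
  "unassigned"
}

#' Classify every read of a sample
#'
#' Runs [accumulate_read()] and [assign_gene()] on each read of a placement
#' set; reads are independent, so the result is order-invariant.
#'
#' @param placements a `nitro_placements` tibble (see [read_jplace()]).
#' @inheritParams accumulate_read
#' @param regions a `nitro_regions`.
#' @return tibble with one row per read: `name`, `multiplicity`, `edge`
#'   (accumulated, `NA` = root sentinel), `label`, `total_mass`, and one
#'   `mass_<gene>` column per target gene.
#' @export
classify_reads <- function(placements, tree, regions, threshold = 0.95,
                           relative = TRUE) {
  targets <- names(regions$nodes)[regions$roles == "target"]
  if (nrow(placements) == 0L) {
    out <- tibble::tibble(name = character(), multiplicity = numeric(),
                          edge = integer(), label = character(),
                          total_mass = numeric())
    for (g in targets) out[[paste0("mass_", g)]] <- numeric(0)
    return(out)
  }
  by_read <- split(placements, placements$name)
  purrr::map_dfr(by_read, function(d) {
    edge <- accumulate_read(tree, d, threshold = threshold, relative = relative)
    m <- region_masses(tree, regions, d)
    M <- sum(d$like_weight_ratio)
    row <- tibble::tibble(
      name = d$name[1], multiplicity = d$multiplicity[1],
      edge = edge,
      label = assign_gene(tree, regions, edge, m, M, threshold = threshold),
      total_mass = M
    )
    for (g in targets) row[[paste0("mass_", g)]] <- m[[g]]
    row
  })
}

#' Count gene fragments in a sample
#'
#' Tallies classified reads per gene (each read contributes its jplace
#' multiplicity to exactly one tally), plus `unassigned` and
#' `dual_discarded`; the tallies sum to the total read multiplicity.
#'
#' @inheritParams classify_reads
#' @return tibble `label`, `count` covering every target gene plus
#'   `unassigned` and `dual_discarded` (zeros included).
#' @export
count_genes <- function(placements, tree, regions, threshold = 0.95,
                        relative = TRUE) {
  targets <- names(regions$nodes)[regions$roles == "target"]
  labels <- c(targets, "unassigned", "dual_discarded")
  calls <- classify_reads(placements, tree, regions, threshold = threshold,
                          relative = relative)
  counts <- calls |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(count = sum(.data$multiplicity), .groups = "drop")
  tibble::tibble(label = labels) |>
    dplyr::left_join(counts, by = "label") |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0))
}
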