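#' Per-edge placement mass profiles for a set of samples
#'
#' Sums likelihood weight ratios onto edges (mass attached at the edge's
#' distal node; sub-edge positions are ignored) and normalizes each sample
#' to total mass 1. The per-sample placement count (number of reads, with
#' multiplicity) is kept for downstream filtering.
#'
#' @param samples named list of `nitro_placements` tibbles
#'   (see [read_jplace()]); names are sample ids.
#' @param tree a [nitro_tree].
#' @return tibble of class `nitro_edge_mass`: `sample`, `edge`, `mass`
#'   (normalized per sample), with attribute `n_placements` (named numeric).
#' @export
edge_mass_profiles <- function(samples, tree) {
  stopifnot(is.list(samples), !is.null(names(samples)))
  out <- purrr::map_dfr(names(samples), function(sid) {
    d <- samples[[sid]]
    if (nrow(d) == 0L) return(tibble::tibble(sample = character(),
                                             edge = integer(), mass = numeric()))
    edge_node(tree, unique(d$edge))
    d |>
      dplyr::group_by(edge = .data$edge) |>
      dplyr::summarise(mass = sum(.data$like_weight_ratio * .data$multiplicity),
                       .groups = "drop") |>
      dplyr::mutate(sample = sid, mass = .data$mass / sum(.data$mass)) |>
      dplyr::select(dplyr::all_of(c("sample", "edge", "mass")))
  })
  n_pl <- vapply(samples, function(d) {
    if (nrow(d) == 0L) 0 else sum(d$multiplicity[!duplicated(d$name)])
  }, numeric(1))
  structure(out, n_placements = n_pl,
            class = c("nitro_edge_mass", class(out)))
}

# distal mass D(v) per node for one sample's normalized edge mass
distal_mass <- function(tree, edge, mass) {
  m <- numeric(tree$n_node)
  m[edge_node(tree, edge)] <- mass
  for (v in tree$postorder) {
    for (ch in tree$children[[v]]) m[v] <- m[v] + m[ch]
  }
  m
}

#' Abundance-weighted phylogenetic diversity (one-parameter family)
#'
#' For a normalized placement mass profile, computes
#' `sum_e l(e) * (2 * min(D(e), 1 - D(e)))^theta` where `D(e)` is the mass
#' on the distal side of edge `e`. `theta = 1` is the fully
#' abundance-weighted form; `theta = 0` counts the branch length of every
#' edge with mass on both sides (classical PD over the mass-spanning
#' subtree, with the convention `0^0 = 0` so one-sided edges drop out).
#'
#' @param tree a [nitro_tree].
#' @param profile tibble with columns `edge`, `mass` for one sample;
#'   masses must be non-negative and sum to 1 (tolerance 1e-6).
#' @param theta abundance weighting exponent in \[0, 1\].
#' @return diversity in branch-length units.
#' @export
bwpd <- function(tree, profile, theta = 1) {
  stopifnot(theta >= 0, theta <= 1)
  if (any(profile$mass < 0) || abs(sum(profile$mass) - 1) > 1e-6) {
    stop("profile must be normalized: non-negative masses summing to 1",
         call. = FALSE)
  }
  D <- distal_mass(tree, profile$edge, profile$mass)
  total <- 0
  for (v in seq_len(tree$n_node)) {
    if (v == tree$root) next
    bal <- 2 * min(D[v], 1 - D[v])
    w <- if (theta == 0) as.numeric(bal > 0) else bal^theta
    total <- total + tree$brlen[v] * w
  }
  total
}

#' Compute BWPD for every sample of an edge-mass profile set
#'
#' @param profiles a `nitro_edge_mass` (see [edge_mass_profiles()]).
#' @param tree a [nitro_tree].
#' @param theta abundance weighting exponent.
#' @return tibble `sample`, `n_placements`, `bwpd`.
#' @export
bwpd_samples <- function(profiles, tree, theta = 1) {
  n_pl <- attr(profiles, "n_placements")
  purrr::map_dfr(split(profiles, profiles$sample), function(d) {
    tibble::tibble(sample = d$sample[1],
                   n_placements = unname(n_pl[d$sample[1]]),
                   bwpd = bwpd(tree, d, theta = theta))
  })
}

#' Edge principal component analysis of placement mass
#'
#' Ordination of samples by where their placement mass sits on the reference
#' tree. For every internal, non-root edge the feature is the mass imbalance
#' `distal - proximal = 2 D(e) - 1`; features are centered across samples
#' and decomposed by PCA. Loadings map back onto tree edges, so components
#' identify the lineages driving compositional variation. Samples with fewer
#' than `min_placements` placements are dropped before the decomposition
#' (imbalances are too noisy below that).
#'
#' @param profiles a `nitro_edge_mass` (see [edge_mass_profiles()]).
#' @param tree a [nitro_tree].
#' @param min_placements minimum per-sample placement count to retain.
#' @return object of class `nitro_edgepca`: list with `projections`
#'   (tibble `sample`, `PC1`..), `loadings` (tibble `edge`, `PC1`..),
#'   `eigenvalues`, `retained`/`dropped` sample ids.
#' @export
edge_pca <- function(profiles, tree, min_placements = 20) {
  n_pl <- attr(profiles, "n_placements")
  keep <- names(n_pl)[n_pl >= min_placements]
  dropped <- setdiff(names(n_pl), keep)
  if (length(keep) < 2L) {
    stop("fewer than 2 samples with >= ", min_placements,
         " placements: edge PCA cannot run", call. = FALSE)
  }
  internal <- which(lengths(tree$children) > 0L)
  internal <- setdiff(internal, tree$root)
  if (length(internal) == 0L) stop("tree has no internal edges", call. = FALSE)
  feat <- do.call(rbind, lapply(keep, function(sid) {
    d <- profiles[profiles$sample == sid, ]
    D <- distal_mass(tree, d$edge, d$mass)
    2 * D[internal] - 1
  }))
  colnames(feat) <- tree$edge_num[internal]
  pc <- stats::prcomp(feat, center = TRUE, scale. = FALSE)
  npc <- ncol(pc$rotation)
  proj <- tibble::as_tibble(pc$x[, seq_len(npc), drop = FALSE])
  proj <- dplyr::bind_cols(tibble::tibble(sample = keep), proj)
  load <- dplyr::bind_cols(
    tibble::tibble(edge = tree$edge_num[internal]),
    tibble::as_tibble(pc$rotation[, seq_len(npc), drop = FALSE])
  )
  structure(
    list(projections = proj, loadings = load,
         eigenvalues = pc$sdev[seq_len(npc)]^2,
         retained = keep, dropped = dropped,
         min_placements = min_placements),
    class = "nitro_edgepca"
  )
}

#' @export
print.nitro_edgepca <- function(x, ...) {
  cat("<nitro_edgepca> ", length(x$retained), " samples (",
      length(x$dropped), " dropped below ", x$min_placements,
      " placements), leading eigenvalues: ",
      paste(format(utils::head(x$eigenvalues, 3), digits = 4), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @method tidy nitro_edgepca
#' @export
tidy.nitro_edgepca <- function(x, ...) x$projections

#' @method glance nitro_edgepca
#' @export
glance.nitro_edgepca <- function(x, ...) {
  tibble::tibble(n_samples = length(x$retained),
                 n_dropped = length(x$dropped),
                 var_pc1 = x$eigenvalues[1] / sum(x$eigenvalues))
}
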