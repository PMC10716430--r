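#' Normalize gene counts by sequencing depth
#'
#' Counts per giga-base-pair sequenced, the depth normalization used for all
#' between-sample gene comparisons.
#'
#' @param count non-negative gene count(s).
#' @param gbp total giga-base-pairs sequenced (> 0), recycled as needed.
#' @return counts per Gbp.
#' @examples
#' normalize_counts(810, 10)
#' @export
normalize_counts <- function(count, gbp) {
  if (any(gbp <= 0)) stop("gbp must be > 0", call. = FALSE)
  if (any(count < 0)) stop("counts must be >= 0", call. = FALSE)
  count / gbp
}

#' The delta nrfA-nir statistic
#'
#' Per-sample difference between ammonification and denitrification nitrite
#' reductase gene counts, normalized by sequencing depth:
#' `(nrfA - (nirK + nirS)) / Gbp`. Positive values indicate a higher genetic
#' potential for NrfA-driven nitrate ammonification than for denitrification,
#' negative values the reverse.
#'
#' @param nrfA,nirK,nirS gene counts (vectors recycled together).
#' @param gbp giga-base-pairs sequenced (> 0).
#' @return delta in counts per Gbp.
#' @examples
#' delta_nrfa_nir(50, 100, 50, gbp = 2)
#' @export
delta_nrfa_nir <- function(nrfA, nirK, nirS, gbp) {
  if (any(gbp <= 0)) stop("gbp must be > 0", call. = FALSE)
  (nrfA - (nirK + nirS)) / gbp
}

#' Build per-sample profiles of normalized counts and delta
#'
#' @param counts tibble with columns `sample`, `nrfA`, `onr`, `nirK`,
#'   `nirS` (raw counts) and `gbp`; extra columns (biome, covariates) are
#'   carried through.
#' @return the input with `nrfA_per_gbp`, `onr_per_gbp`, `nirK_per_gbp`,
#'   `nirS_per_gbp` and `delta_nrfa_nir` appended.
#' @export
quantify_profiles <- function(counts) {
  need <- c("sample", "nrfA", "nirK", "nirS", "gbp")
  miss <- setdiff(need, names(counts))
  if (length(miss) > 0L) {
    stop("profile table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(counts) |>
    dplyr::mutate(
      nrfA_per_gbp = normalize_counts(.data$nrfA, .data$gbp),
      nirK_per_gbp = normalize_counts(.data$nirK, .data$gbp),
      nirS_per_gbp = normalize_counts(.data$nirS, .data$gbp),
      delta_nrfa_nir = delta_nrfa_nir(.data$nrfA, .data$nirK, .data$nirS, .data$gbp)
    )
  if ("onr" %in% names(counts)) {
    out <- dplyr::mutate(out, onr_per_gbp = normalize_counts(.data$onr, .data$gbp))
  }
  out
}

#' Kruskal-Wallis test with rank-based LSD multiple comparisons
#'
#' Tie-corrected Kruskal-Wallis H across groups (via [stats::kruskal.test()]),
#' followed by pairwise Fisher least-significant-difference tests on mean
#' ranks: the t statistic uses the pooled rank variance deflated by
#' `(N - 1 - H)/(N - k)` with `N - k` degrees of freedom. Pairwise p-values
#' are Benjamini-Hochberg adjusted, and groups are summarized with an
#' insert-and-absorb compact letter display (groups sharing a letter do not
#' differ at `alpha`), lettered from the highest mean rank down.
#'
#' @param data a data frame.
#' @param value name of the numeric response column.
#' @param group name of the grouping column.
#' @param alpha significance level for the letter display.
#' @return object of class `nitro_kw`: list with `statistic` (H), `df`,
#'   `p.value`, `groups` tibble (`group`, `n`, `median`, `mean_rank`,
#'   `letters`), and `comparisons` tibble of pairwise tests.
#'   [generics::tidy()] returns the comparisons, [generics::glance()] the
#'   omnibus test.
#' @examples
#' d <- data.frame(v = c(1, 2, 3, 10, 11, 12), g = rep(c("a", "b"), each = 3))
#' group_compare(d, "v", "g")
#' @export
group_compare <- function(data, value, group, alpha = 0.05) {
  x <- data[[value]]
  g <- factor(data[[group]])
  ok <- stats::complete.cases(x, g)
  x <- x[ok]; g <- droplevels(g[ok])
  k <- nlevels(g)
  if (k < 2L) stop("need at least two groups", call. = FALSE)
  N <- length(x)
  kw <- stats::kruskal.test(x, g)
  H <- unname(kw$statistic)
  r <- rank(x)
  S2 <- stats::var(r)
  mean_rank <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  levs <- levels(g)
  comps <- tidyr::crossing(i = seq_len(k), j = seq_len(k)) |>
    dplyr::filter(.data$i < .data$j) |>
    dplyr::mutate(
      group1 = levs[.data$i], group2 = levs[.data$j],
      diff = mean_rank[.data$i] - mean_rank[.data$j],
      se = sqrt(S2 * ((N - 1 - H) / (N - k)) *
                  (1 / n_g[.data$i] + 1 / n_g[.data$j])),
      statistic = .data$diff / .data$se,
      p.value = 2 * stats::pt(-abs(.data$statistic), df = N - k)
    ) |>
    dplyr::mutate(p.adjust = stats::p.adjust(.data$p.value, method = "BH")) |>
    dplyr::select(dplyr::all_of(c("group1", "group2", "diff", "se",
                                  "statistic", "p.value", "p.adjust")))
  different <- matrix(FALSE, k, k, dimnames = list(levs, levs))
  for (i in seq_len(nrow(comps))) {
    d <- comps$p.adjust[i] < alpha
    different[comps$group1[i], comps$group2[i]] <- d
    different[comps$group2[i], comps$group1[i]] <- d
  }
  ord <- order(mean_rank, decreasing = TRUE)
  letters_cld <- cld_insert_absorb(different, levs[ord])
  groups <- tibble::tibble(
    group = levs,
    n = as.integer(n_g),
    median = as.numeric(tapply(x, g, stats::median)),
    mean_rank = as.numeric(mean_rank),
    letters = unname(letters_cld[levs])
  )
  structure(
    list(statistic = H, df = k - 1L, p.value = kw$p.value,
         alpha = alpha, groups = groups, comparisons = comps,
         value = value, group = group),
    class = "nitro_kw"
  )
}

# insert-and-absorb compact letter display.
# `different`: symmetric logical matrix; `order`: group names, best first.
# Start from one letter covering everything; for every significantly
# different pair split each column containing both; absorb subset columns.
cld_insert_absorb <- function(different, order) {
  cols <- list(order)
  absorb <- function(cols) {
    drop <- rep(FALSE, length(cols))
    for (a in seq_along(cols)) {
      for (b in seq_along(cols)) {
        if (a != b && !drop[a] && !drop[b] &&
            all(cols[[a]] %in% cols[[b]])) drop[a] <- TRUE
      }
    }
    cols[!drop]
  }
  for (i in seq_along(order)) {
    for (j in seq_along(order)) {
      if (i < j && different[order[i], order[j]]) {
        gi <- order[i]; gj <- order[j]
        newcols <- list()
        for (col in cols) {
          if (gi %in% col && gj %in% col) {
            newcols <- c(newcols, list(setdiff(col, gi)), list(setdiff(col, gj)))
          } else {
            newcols <- c(newcols, list(col))
          }
        }
        cols <- absorb(newcols)
      }
    }
  }
  cols <- cols[order(vapply(cols, function(cc) min(match(cc, order)), numeric(1)))]
  out <- stats::setNames(rep("", length(order)), order)
  for (ci in seq_along(cols)) {
    for (gname in cols[[ci]]) out[gname] <- paste0(out[gname], letters[ci])
  }
  out
}

#' @export
print.nitro_kw <- function(x, ...) {
  cat("Kruskal-Wallis: H(", x$df, ") = ", format(x$statistic, digits = 4),
      ", p = ", format(x$p.value, digits = 3), "\n", sep = "")
  print(x$groups)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy nitro_kw
#' @export
tidy.nitro_kw <- function(x, ...) x$comparisons

#' @method glance nitro_kw
#' @export
glance.nitro_kw <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
                 method = "Kruskal-Wallis with rank LSD / BH letters")
}

#' Wilcoxon-Mann-Whitney two-group test
#'
#' Two-sided; exact when both groups have at most 25 observations and there
#' are no ties, normal approximation with continuity correction otherwise.
#'
#' @param x,y numeric vectors (non-empty).
#' @return the two-sided p-value.
#' @export
two_group_test <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty group", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- length(x) <= 25 && length(y) <= 25 && !ties
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value
  )
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks; constant input is an error
#' (the coefficient is undefined there).
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return rho in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector: Spearman correlation undefined", call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}
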