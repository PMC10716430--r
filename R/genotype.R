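#' Classify assemblies by co-occurrence of ammonification and
#' denitrification genes
#'
#' Works on a gene presence/absence table for assemblies recovered when
#' screening genomes for the ammonification markers `nrfA` and `onr`. Each
#' row must carry at least one of the two (rows outside the cohort are an
#' error). Denitrification is counted by gene family: `nir` (= `nirK` or
#' `nirS`), `nor`, and `nosZ` (= clade I or clade II).
#'
#' Derived flags:
#' \describe{
#'   \item{ammonifier_type}{`nrfA_only`, `onr_only`, or `nrfA_and_onr`}
#'   \item{n_denit_genes}{number of denitrification families present (0-3)}
#'   \item{has_denit / multi_denit}{at least one / more than one family}
#'   \item{complete_denitrifier}{`nir` and `nor` and `nosZ` all present
#'     (the full nitrite-to-N2 pathway)}
#'   \item{n2o_producer}{`nor` without `nosZ` (potential net N2O source)}
#'   \item{n2o_consumer}{`nosZ` present, alone or with `nir`/`nor`
#'     (potential N2O sink)}
#' }
#'
#' @param tbl tibble/data frame with logical (or 0/1) columns `nrfA`, `onr`,
#'   `nirK`, `nirS`, `nor`, `nosZ_cladeI`, `nosZ_cladeII`; other columns
#'   (e.g. `assembly`, taxonomy) are carried through.
#' @return the input tibble with the derived columns appended.
#' @export
classify_genotypes <- function(tbl) {
  need <- c("nrfA", "onr", "nirK", "nirS", "nor", "nosZ_cladeI", "nosZ_cladeII")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0L) {
    stop("gene table lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  tbl <- tibble::as_tibble(tbl) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(need), as.logical))
  if (any(!tbl$nrfA & !tbl$onr)) {
    stop("row(s) with neither nrfA nor onr: the cohort is defined by ",
         "screening for these genes", call. = FALSE)
  }
  tbl |>
    dplyr::mutate(
      ammonifier_type = dplyr::case_when(
        .data$nrfA & .data$onr ~ "nrfA_and_onr",
        .data$nrfA ~ "nrfA_only",
        TRUE ~ "onr_only"
      ),
      nir = .data$nirK | .data$nirS,
      nosZ = .data$nosZ_cladeI | .data$nosZ_cladeII,
      n_denit_genes = as.integer(.data$nir) + as.integer(.data$nor) +
        as.integer(.data$nosZ),
      has_denit = .data$n_denit_genes >= 1L,
      multi_denit = .data$n_denit_genes > 1L,
      complete_denitrifier = .data$nir & .data$nor & .data$nosZ,
      n2o_producer = .data$nor & !.data$nosZ,
      n2o_consumer = .data$nosZ
    )
}

#' Summarize denitrification potential across an ammonifier cohort
#'
#' Per ammonifier type (and optionally per taxonomic group), reports the
#' fraction of assemblies with at least one, more than one, and the complete
#' set of denitrification gene families, and — among assemblies with any
#' denitrification gene — the fractions of potential N2O producers,
#' consumers, and `nir`-only carriers (a partition). Denominators accompany
#' every fraction.
#'
#' @param tbl a gene presence table (see [classify_genotypes()]; raw tables
#'   are classified on the fly).
#' @param by optional character: an extra grouping column (e.g. `"class"`).
#' @return tibble with one row per group: `n`, `frac_has_denit`,
#'   `frac_multi_denit`, `frac_complete`, `n_has_denit`, `frac_n2o_producer`,
#'   `frac_n2o_consumer`, `frac_nir_only`.
#' @export
summarize_cohort <- function(tbl, by = NULL) {
  if (nrow(tbl) == 0L) stop("empty gene table", call. = FALSE)
  if (!"has_denit" %in% names(tbl)) tbl <- classify_genotypes(tbl)
  groups <- c("ammonifier_type", by)
  tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(
      n = dplyr::n(),
      frac_has_denit = mean(.data$has_denit),
      frac_multi_denit = mean(.data$multi_denit),
      frac_complete = mean(.data$complete_denitrifier),
      n_has_denit = sum(.data$has_denit),
      frac_n2o_producer = ifelse(n_has_denit > 0,
                                 sum(.data$n2o_producer) / n_has_denit, NA_real_),
      frac_n2o_consumer = ifelse(n_has_denit > 0,
                                 sum(.data$n2o_consumer) / n_has_denit, NA_real_),
      frac_nir_only = ifelse(n_has_denit > 0,
                             sum(.data$has_denit & !.data$nor & !.data$nosZ) /
                               n_has_denit, NA_real_),
      .groups = "drop"
    )
}
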