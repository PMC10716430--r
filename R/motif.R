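AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

check_aa <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  bad <- setdiff(unique(strsplit(s, "")[[1]]), c(AA_ALPHABET, "X"))
  if (length(bad) > 0L) {
    stop("non-amino-acid characters in sequence: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  s
}

#' Scan an amino-acid sequence for heme-binding sites
#'
#' Finds C-X-X-C-\[H|K\] windows (the heme c attachment motif of multiheme
#' cytochromes) by a greedy left-to-right scan: each accepted 5-residue site
#' blocks overlapping windows, mimicking how sites are read off an alignment.
#' `X` (unknown residue) never matches C, H or K.
#'
#' @param seq amino-acid string (20-letter alphabet plus X, case-insensitive).
#' @return tibble with one row per site: `start` (0-based), `kind`
#'   (`"CXXCH"` or `"CXXCK"`).
#' @examples
#' scan_heme_sites("MCAACKGGCAACHGG")
#' @export
scan_heme_sites <- function(seq) {
  s <- strsplit(check_aa(seq), "")[[1]]
  n <- length(s)
  start <- integer(0); kind <- character(0)
  i <- 1L
  while (i <= n - 4L) {
    if (s[i] == "C" && s[i + 3L] == "C" && s[i + 4L] %in% c("H", "K")) {
      start <- c(start, i - 1L)
      kind <- c(kind, paste0("CXXC", s[i + 4L]))
      i <- i + 5L
    } else {
      i <- i + 1L
    }
  }
  tibble::tibble(start = start, kind = kind)
}

# residues strictly between site i and site i+1 (1-based site indices)
inter_site_segment <- function(s, sites, i) {
  from <- sites$start[i] + 5L + 1L      # 1-based position after site i
  to <- sites$start[i + 1L]             # 1-based position before site i+1
  if (from > to) return("")
  substr(s, from, to)
}

#' Classify a candidate nitrite reductase sequence by motif architecture
#'
#' Applies the curation rules for the pentaheme (NrfA) and octaheme (ONR)
#' ammonia-forming nitrite reductases:
#' \itemize{
#' \item NrfA: exactly five heme-binding sites with a histidine strictly
#'   between sites 3 and 4. First site C-X-X-C-K is the canonical form;
#'   C-X-X-C-H marks the CXXCH clade. Calcium independence is flagged by an
#'   Arg-His dipeptide in the segment between sites 3 and 4 (that His also
#'   satisfies the interstitial requirement).
#' \item ONR: exactly eight sites in the pattern 3x-CXXCH, 1x-CXXCK,
#'   4x-CXXCH with a histidine strictly between sites 6 and 7; always
#'   calcium-dependent.
#' }
#' Anything else is `nontarget`.
#'
#' @param seq amino-acid string.
#' @return one-row tibble: `class` (`NrfA_canonical`, `NrfA_CXXCH_clade`,
#'   `ONR`, `nontarget`), `calcium_dependent` (logical, `NA` for nontarget),
#'   `n_sites`, `sites` (list column with the site tibble).
#' @export
classify_sequence <- function(seq) {
  s <- check_aa(seq)
  sites <- scan_heme_sites(s)
  out <- function(class, ca) {
    tibble::tibble(class = class, calcium_dependent = ca,
                   n_sites = nrow(sites), sites = list(sites))
  }
  if (nrow(sites) == 5L) {
    seg34 <- inter_site_segment(s, sites, 3L)
    if (grepl("H", seg34, fixed = TRUE)) {
      cls <- if (sites$kind[1] == "CXXCK") "NrfA_canonical" else "NrfA_CXXCH_clade"
      return(out(cls, !grepl("RH", seg34, fixed = TRUE)))
    }
  }
  if (nrow(sites) == 8L &&
      identical(sites$kind, paste0("CXXC", c("H", "H", "H", "K", "H", "H", "H", "H")))) {
    seg67 <- inter_site_segment(s, sites, 6L)
    if (grepl("H", seg67, fixed = TRUE)) return(out("ONR", TRUE))
  }
  out("nontarget", NA)
}

#' Classify many sequences at once
#'
#' @param seqs named character vector of amino-acid sequences.
#' @return tibble with `id` plus the columns of [classify_sequence()].
#' @export
classify_sequences <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L, !is.null(names(seqs)))
  purrr::map_dfr(names(seqs), function(id) {
    dplyr::bind_cols(tibble::tibble(id = id), classify_sequence(seqs[[id]]))
  })
}

#' Dereplicate sequences at 100% identity
#'
#' Collapses exact duplicates after uppercasing; the representative of each
#' duplicate group is the lexicographically smallest label (C collation, so
#' the choice is locale-independent).
#'
#' @param seqs named character vector.
#' @return list with `unique` (tibble `representative`, `sequence`, `n`) and
#'   `map` (tibble `id`, `representative`).
#' @export
dereplicate <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L, !is.null(names(seqs)))
  d <- tibble::tibble(id = names(seqs), sequence = toupper(unname(seqs)))
  d <- d |>
    dplyr::group_by(.data$sequence) |>
    dplyr::mutate(representative = sort(.data$id, method = "radix")[1]) |>
    dplyr::ungroup()
  uni <- d |>
    dplyr::distinct(.data$representative, .data$sequence) |>
    dplyr::left_join(dplyr::count(d, .data$representative), by = "representative") |>
    dplyr::arrange(.data$representative)
  list(unique = uni, map = d[, c("id", "representative")])
}

pairwise_identity <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  if (length(x) != length(y)) {
    stop("sequences differ in length; align them first (identity is defined ",
         "on alignment columns)", call. = FALSE)
  }
  keep <- !(x == "-" & y == "-")
  if (!any(keep)) return(NA_real_)
  mean(x[keep] == y[keep]) * 100
}

#' Report assemblies carrying multiple gene copies
#'
#' For assemblies with more than one copy of a gene, reports the copy count
#' and the mean pairwise percent identity among copies. Identity is computed
#' on aligned, equal-length sequences as matching columns over columns that
#' are not gaps in both copies; unaligned input of unequal length is an error.
#'
#' @param copies tibble with columns `assembly`, `id`, `sequence`.
#' @return tibble `assembly`, `n_copies`, `mean_identity` (percent), sorted
#'   by assembly; single-copy assemblies are excluded.
#' @export
multicopy_report <- function(copies) {
  stopifnot(all(c("assembly", "id", "sequence") %in% names(copies)))
  copies |>
    dplyr::group_by(.data$assembly) |>
    dplyr::filter(dplyr::n() > 1L) |>
    dplyr::summarise(
      n_copies = dplyr::n(),
      mean_identity = {
        ss <- toupper(.data$sequence)
        pairs <- utils::combn(seq_along(ss), 2)
        mean(apply(pairs, 2, function(p) pairwise_identity(ss[p[1]], ss[p[2]])))
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$assembly)
}
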