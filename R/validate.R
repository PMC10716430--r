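#' Fragment reference sequences for in-silico validation
#'
#' Cuts labeled reference sequences into fixed-length fragments (150 nt or
#' 50 aa, the longest peptide predictable from a 150 nt read), sampling the
#' source sequence and the start offset uniformly. Deterministic under a
#' seed; no sequencing-error model is applied (validation uses error-free
#' fragments).
#'
#' @param seqs named character vector of sequences (nt or aa).
#' @param n number of fragments to draw.
#' @param length fragment length in the sequences' units.
#' @param seed integer seed.
#' @return tibble: `fragment`, `source`, `start` (0-based), `sequence`.
#' @export
fragment_sequences <- function(seqs, n, length = 150L, seed = 1L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), n >= 1L)
  short <- names(seqs)[nchar(seqs) < length]
  if (length(short) > 0L) {
    stop("sequence(s) shorter than the fragment length: ",
         paste(short, collapse = ", "), call. = FALSE)
  }
  withr_seed(seed)
  src <- sample(names(seqs), n, replace = TRUE)
  start <- vapply(src, function(id) {
    sample.int(nchar(seqs[[id]]) - length + 1L, 1L) - 1L
  }, integer(1))
  tibble::tibble(
    fragment = sprintf("frag_%06d", seq_len(n)),
    source = src,
    start = unname(start),
    sequence = substr(seqs[src], start + 1L, start + length)
  )
}

# local seed without clobbering the caller's RNG state
withr_seed <- function(seed) {
  set.seed(as.integer(seed))
  invisible(NULL)
}

#' Sensitivity and specificity of fragment classification
#'
#' Per gene `g`: sensitivity is the fraction of true-`g` fragments assigned
#' `g` (unplaced or misassigned fragments count against it); specificity is
#' one minus the fraction of true non-`g` fragments assigned `g` (unplaced
#' fragments do not count against specificity).
#'
#' @param truth named character: fragment id -> true gene.
#' @param assignments named character: fragment id -> assigned label
#'   (gene, `"unassigned"`, `"dual_discarded"`, or `"unplaced"`).
#' @return tibble `gene`, `n_true`, `sensitivity`, `n_other`, `specificity`.
#' @export
confusion_metrics <- function(truth, assignments) {
  if (!setequal(names(truth), names(assignments))) {
    stop("truth and assignments must cover the same fragment ids", call. = FALSE)
  }
  a <- assignments[names(truth)]
  purrr::map_dfr(sort(unique(truth)), function(g) {
    is_g <- truth == g
    tibble::tibble(
      gene = g,
      n_true = sum(is_g),
      sensitivity = mean(a[is_g] == g),
      n_other = sum(!is_g),
      specificity = if (any(!is_g)) 1 - mean(a[!is_g] == g) else NA_real_
    )
  })
}

#' False-positive rates for decoy (non-target homolog) fragments
#'
#' Fragments of distant multiheme cytochrome homologs should mostly fail to
#' place at all, and almost never land in the focal gene region.
#'
#' @param assignments named character: decoy fragment id -> label
#'   (`"unplaced"` for fragments that received no placement).
#' @param focal focal gene label (or a vector of labels counted as focal).
#' @return tibble `n_decoys`, `frac_placed`, `frac_in_focal`.
#' @export
decoy_rate <- function(assignments, focal) {
  stopifnot(length(assignments) >= 1L)
  tibble::tibble(
    n_decoys = length(assignments),
    frac_placed = mean(assignments != "unplaced"),
    frac_in_focal = mean(assignments %in% focal)
  )
}
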