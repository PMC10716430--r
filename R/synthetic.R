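#' Generate amino-acid sequences with planted heme-motif architectures
#'
#' Background residues are drawn uniformly from the 19 amino acids other
#' than cysteine, so no accidental C-X-X-C-\[H|K\] window can arise and the
#' planted site count is exact. Classes:
#' `NrfA_canonical` (5 sites, first C-X-X-C-K, His between sites 3 and 4),
#' `NrfA_CXXCH_clade` (5 sites, first C-X-X-C-H),
#' `ONR` (8 sites, 3x-CXXCH / 1x-CXXCK / 4x-CXXCH, His between sites 6 and
#' 7), and `nontarget` (motif-free decoys). For NrfA classes,
#' `calcium_dependent = FALSE` plants an Arg-His dipeptide between sites 3
#' and 4 instead of a lone His.
#'
#' @param class one of `"NrfA_canonical"`, `"NrfA_CXXCH_clade"`, `"ONR"`,
#'   `"nontarget"`.
#' @param n number of sequences.
#' @param spacer length of each inter-site segment (>= 3).
#' @param calcium_dependent plant calcium dependence (NrfA classes only).
#' @param seed integer seed.
#' @param prefix id prefix.
#' @return named character vector of sequences.
#' @export
simulate_motif_sequences <- function(class = c("NrfA_canonical", "NrfA_CXXCH_clade",
                                               "ONR", "nontarget"),
                                     n = 10, spacer = 12, calcium_dependent = TRUE,
                                     seed = 1L, prefix = class) {
  class <- match.arg(class)
  stopifnot(spacer >= 3, n >= 1)
  set.seed(as.integer(seed))
  bg <- setdiff(AA_ALPHABET, "C")
  bg_plain <- setdiff(bg, c("H", "R")) # segments whose H/R content is controlled
  rand <- function(k, alphabet) paste(sample(alphabet, k, replace = TRUE), collapse = "")
  site <- function(kind) paste0("C", rand(2, bg_plain), "C", kind)
  seqs <- vapply(seq_len(n), function(i) {
    if (class == "nontarget") {
      return(rand(5L * 5L + 6L * spacer, bg_plain))
    }
    kinds <- switch(class,
      NrfA_canonical = c("K", "H", "H", "H", "H"),
      NrfA_CXXCH_clade = c("H", "H", "H", "H", "H"),
      ONR = c("H", "H", "H", "K", "H", "H", "H", "H")
    )
    his_after <- if (class == "ONR") 6L else 3L
    pieces <- rand(spacer, bg_plain) # leading segment
    for (s in seq_along(kinds)) {
      pieces <- c(pieces, site(kinds[s]))
      if (s < length(kinds)) {
        seg <- rand(spacer - 2L, bg_plain)
        if (s == his_after) {
          mark <- if (class != "ONR" && !calcium_dependent) "RH" else "GH"
          seg <- paste0(substr(seg, 1, spacer - 4L), mark,
                        substr(seg, spacer - 3L, spacer - 2L))
        } else {
          seg <- paste0(seg, rand(2L, bg_plain))
        }
        pieces <- c(pieces, seg)
      }
    }
    pieces <- c(pieces, rand(spacer, bg_plain)) # trailing segment
    paste(pieces, collapse = "")
  }, character(1))
  stats::setNames(seqs, sprintf("%s_%03d", prefix, seq_len(n)))
}

#' Simulate a reference package with labeled monophyletic gene regions
#'
#' Builds a rooted reference tree whose gene regions are monophyletic by
#' construction: one coalescent-shaped clade per gene, attached to a
#' backbone, with the first listed outgroup-role region sister to the rest.
#' Reference peptides with the matching planted motif class are generated
#' for `nrfA` (canonical), `onr`, and motif-free sequences for all other
#' regions.
#'
#' @param tips named integer vector: region label -> number of tips
#'   (each >= 2). Regions named `outgroup*` get the outgroup role.
#' @param seed integer seed.
#' @return list of class `nitro_refpkg`: `tree` (a [nitro_tree]),
#'   `regions` (a `nitro_regions`), `sequences` (named character),
#'   `classes` (tibble `id`, `gene`, `class`).
#' @export
simulate_refpkg <- function(tips = c(nrfA = 8, onr = 4, nirK = 4, nirS = 4,
                                     outgroup = 4),
                            seed = 1L) {
  stopifnot(!is.null(names(tips)), all(tips >= 2))
  set.seed(as.integer(seed))
  genes <- names(tips)
  clade_nwk <- vapply(genes, function(g) {
    phy <- ape::rcoal(tips[[g]],
                      tip.label = sprintf("%s_t%02d", g, seq_len(tips[[g]])))
    phy$edge.length <- phy$edge.length / max(ape::node.depth.edgelength(phy))
    sub(";$", "", ape::write.tree(phy))
  }, character(1))
  # one monophyletic clade per region, all hanging off the root
  tree <- parse_newick(
    paste0("(", paste0(clade_nwk, ":0.5", collapse = ","), ");"))
  roles <- stats::setNames(
    ifelse(grepl("^outgroup", genes), "outgroup", "target"), genes)
  tip_sets <- lapply(genes, function(g) {
    sprintf("%s_t%02d", g, seq_len(tips[[g]]))
  })
  names(tip_sets) <- genes
  regions <- label_regions(tree, tip_sets, roles = roles)
  seq_class <- function(g) {
    switch(g, nrfA = "NrfA_canonical", onr = "ONR", "nontarget")
  }
  sequences <- character(0)
  classes <- NULL
  for (i in seq_along(genes)) {
    g <- genes[i]
    s <- simulate_motif_sequences(seq_class(g), n = tips[[g]],
                                  seed = as.integer(seed) + i, prefix = g)
    names(s) <- tip_sets[[g]]
    sequences <- c(sequences, s)
    classes <- dplyr::bind_rows(
      classes, tibble::tibble(id = names(s), gene = g, class = seq_class(g)))
  }
  structure(list(tree = tree, regions = regions, sequences = sequences,
                 classes = classes, seed = as.integer(seed)),
            class = "nitro_refpkg")
}

#' @export
print.nitro_refpkg <- function(x, ...) {
  cat("<nitro_refpkg> ", x$tree$n_tip, " tips\n", sep = "")
  print(x$regions$genes)
  invisible(x)
}

#' Simulate a sample of placed reads with known gene labels
#'
#' Draws reads per gene according to `composition`. A read's likelihood
#' weight ratios are a symmetric Dirichlet draw (concentration `1/spread`)
#' over up to 7 edges of its true region, mirroring placement tools that
#' report at most seven candidate placements; `spread = 0` collapses to a
#' single edge with mass 1. With probability `cross_region_rate` a read
#' leaks `1 - threshold + 0.01` of its mass onto another target region
#' (falling back to an outgroup region when there is no second target),
#' which forces the dual-gene discard downstream.
#'
#' @param refpkg a `nitro_refpkg` (see [simulate_refpkg()]).
#' @param composition named numeric: gene -> number of reads; names must be
#'   target regions of the reference package.
#' @param spread within-region placement dispersion (>= 0).
#' @param cross_region_rate probability of a cross-region mass leak in
#'   \[0, 1\].
#' @param gbp giga-base-pairs "sequenced" for the sample (metadata only).
#' @param threshold accumulation threshold the leak is calibrated against.
#' @param sample sample id.
#' @param seed integer seed.
#' @return list with `placements` (a `nitro_placements` tibble), `truth`
#'   (tibble `name`, `gene`, `leaked`), `gbp`, `delta_true`
#'   (`(nrfA - (nirK + nirS)) / gbp` of the drawn composition, `NA` when
#'   those genes are absent), and `sample`.
#' @export
simulate_placements <- function(refpkg, composition, spread = 0,
                                cross_region_rate = 0, gbp = 1,
                                threshold = 0.95, sample = "sample_1",
                                seed = 1L) {
  stopifnot(inherits(refpkg, "nitro_refpkg"), spread >= 0,
            cross_region_rate >= 0, cross_region_rate <= 1, gbp > 0)
  if (any(composition < 0)) stop("composition counts must be >= 0", call. = FALSE)
  tree <- refpkg$tree
  regions <- refpkg$regions
  targets <- names(regions$nodes)[regions$roles == "target"]
  bad <- setdiff(names(composition), targets)
  if (length(bad) > 0L) {
    stop("composition names not target regions: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  rows <- list(); truth <- list(); read_i <- 0L
  leak_mass <- 1 - threshold + 0.01
  for (g in names(composition)) {
    n_reads <- composition[[g]]
    own_edges <- tree$edge_num[regions$nodes[[g]]]
    for (r in seq_len(n_reads)) {
      read_i <- read_i + 1L
      name <- sprintf("%s_read_%05d", g, read_i)
      k <- if (spread == 0) 1L else min(7L, length(own_edges))
      edges <- sample(own_edges, k)
      w <- if (k == 1L) 1 else {
        a <- stats::rgamma(k, shape = 1 / spread)
        if (sum(a) == 0) rep(1 / k, k) else a / sum(a)
      }
      leaked <- stats::runif(1) < cross_region_rate
      if (leaked) {
        foreign <- setdiff(targets, g)
        pool <- if (length(foreign) > 0L) foreign else
          names(regions$nodes)[regions$roles == "outgroup"]
        if (length(pool) == 0L) stop("no region available to leak into", call. = FALSE)
        fg <- if (length(pool) == 1L) pool else sample(pool, 1)
        f_edge <- regions$nodes[[fg]]
        f_edge <- tree$edge_num[if (length(f_edge) == 1L) f_edge else sample(f_edge, 1)]
        w <- w * (1 - leak_mass)
        edges <- c(edges, f_edge)
        w <- c(w, leak_mass)
      }
      rows[[read_i]] <- tibble::tibble(
        name = name, multiplicity = 1, edge = as.integer(edges),
        like_weight_ratio = w, likelihood = -100 + log(w + 1e-12)
      )
      truth[[read_i]] <- tibble::tibble(name = name, gene = g, leaked = leaked)
    }
  }
  placements <- dplyr::bind_rows(rows)
  if (is.null(placements) || nrow(placements) == 0L) {
    placements <- tibble::tibble(name = character(), multiplicity = numeric(),
                                 edge = integer(), like_weight_ratio = numeric(),
                                 likelihood = numeric())
  }
  placements <- structure(placements, sample = sample,
                          class = c("nitro_placements", class(placements)))
  comp <- function(g) if (g %in% names(composition)) composition[[g]] else NA_real_
  delta_true <- if (all(c("nrfA", "nirK", "nirS") %in% names(composition))) {
    delta_nrfa_nir(comp("nrfA"), comp("nirK"), comp("nirS"), gbp)
  } else NA_real_
  list(placements = placements,
       truth = dplyr::bind_rows(truth) %||% tibble::tibble(),
       gbp = gbp, delta_true = delta_true, sample = sample)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate sample metadata with planted biome and soil effects
#'
#' Draws soil covariates uniformly within field-realistic ranges
#' (continental soil-survey spans: pH 4.0-9.6, nitrate 1-59 mg/kg, organic
#' carbon 0.1-5.9%, etc.), assigns biomes, and builds the response as
#' `delta = sum of planted effects + biome offset + Gaussian noise`. The
#' default planted effect is a saturating increase with `log(SOC/nitrate)`,
#' the electron donor/acceptor balance expected to favor ammonifiers.
#'
#' @param n number of samples (>= 30).
#' @param biomes named numeric: biome label -> additive offset on delta.
#' @param effects named list of single-argument functions: covariate ->
#'   partial effect on delta (covariate must exist).
#' @param noise_sd standard deviation of the Gaussian noise.
#' @param ranges named list of `c(min, max)` covariate ranges.
#' @param seed integer seed.
#' @return list with `data` (tibble: `sample`, `biome`, covariates,
#'   `delta_nrfa_nir`) and `truth` (list: `effects`, `biomes`, `noise_sd`,
#'   `expected` tibble of noiseless responses).
#' @export
simulate_metadata <- function(n = 227,
                              biomes = c(Cropland = -40, Desert = -10,
                                         Forest = 15, Grassland = 10),
                              effects = list(
                                soc_nitrate = function(d) {
                                  30 * tanh(log(d$organic_carbon / d$nitrate) + 2)
                                }
                              ),
                              noise_sd = 10,
                              ranges = list(
                                ammonium = c(0.0, 87.0),
                                phosphorus = c(2.0, 193.0),
                                calcium = c(0.6, 158.1),
                                clay = c(0.8, 65.3),
                                copper = c(0.0, 32.7),
                                moisture = c(0.0, 103.3),
                                nitrate = c(1.0, 59.0),
                                ph = c(4.0, 9.6),
                                organic_carbon = c(0.1, 5.9),
                                sulfur = c(0.7, 724.6),
                                elevation = c(1.0, 1350.0)
                              ),
                              seed = 1L) {
  if (n < 30) stop("need at least 30 samples", call. = FALSE)
  if (length(biomes) == 0L || is.null(names(biomes))) {
    stop("biomes must be a named offset vector", call. = FALSE)
  }
  set.seed(as.integer(seed))
  d <- tibble::tibble(sample = sprintf("meta_%04d", seq_len(n)))
  for (v in names(ranges)) {
    d[[v]] <- stats::runif(n, ranges[[v]][1], ranges[[v]][2])
  }
  d$biome <- factor(sample(names(biomes), n, replace = TRUE),
                    levels = names(biomes))
  planted <- rep(0, n)
  for (f in effects) planted <- planted + f(d)
  expected <- planted + unname(biomes[as.character(d$biome)])
  d$delta_nrfa_nir <- expected + stats::rnorm(n, sd = noise_sd)
  list(
    data = d,
    truth = list(effects = effects, biomes = biomes, noise_sd = noise_sd,
                 expected = tibble::tibble(sample = d$sample, expected = expected))
  )
}
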