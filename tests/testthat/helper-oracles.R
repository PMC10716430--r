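# Independent oracles and fixture builders shared across tests.
# These use only the public fields of nitroplace objects, never the
# package's own traversal helpers, so they stay independent of the code
# paths they check.

# Exhaustive accumulation oracle: for every non-root edge, collect the edges
# of its subtree by a fresh breadth-first walk, sum the read's mass on them,
# and return the deepest edge whose distal mass reaches the threshold.
oracle_accumulate <- function(tree, placements, threshold, relative = TRUE) {
  node_of <- match(placements$edge, tree$edge_num)
  stopifnot(!anyNA(node_of))
  M <- sum(placements$like_weight_ratio)
  target <- threshold * (if (relative) M else 1)
  best <- NA_integer_; best_depth <- -1L
  for (v in seq_len(tree$n_node)) {
    if (v == tree$root) next
    sub <- integer(0); queue <- v
    while (length(queue) > 0L) {
      x <- queue[1L]; queue <- queue[-1L]
      sub <- c(sub, x)
      queue <- c(queue, tree$children[[x]])
    }
    S <- sum(placements$like_weight_ratio[node_of %in% sub])
    if (S >= target - 1e-12 && tree$depth[v] > best_depth) {
      best <- v; best_depth <- tree$depth[v]
    }
  }
  if (is.na(best)) NA_integer_ else tree$edge_num[best]
}

# Random rooted tree with jplace numbering (via ape, converted)
random_tree <- function(n_tips) {
  as_nitro_tree(ape::rtree(n_tips))
}

# Random placement vector for one read: <= 7 edges, Dirichlet weights,
# total mass possibly < 1 (placement mass loss)
random_read <- function(tree, max_edges = 7L, mass_loss = TRUE) {
  k <- sample.int(min(max_edges, tree$n_node - 1L), 1L)
  edges <- sample(tree$edge_num[-tree$root], k)
  w <- rgamma(k, shape = 1)
  w <- w / sum(w) * (if (mass_loss) runif(1, 0.7, 1) else 1)
  tibble::tibble(name = "r1", multiplicity = 1, edge = edges,
                 like_weight_ratio = w, likelihood = NA_real_)
}

# Brute-force heme-site oracle: test every window with a vectorized
# predicate, then apply the left-to-right non-overlap rule.
oracle_heme_sites <- function(seq) {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  ok <- vapply(seq_len(max(0L, n - 4L)), function(i) {
    s[i] == "C" && s[i + 3L] == "C" && s[i + 4L] %in% c("H", "K")
  }, logical(1))
  starts <- integer(0); last_end <- 0L
  for (i in seq_along(ok)) {
    if (ok[i] && i > last_end) {
      starts <- c(starts, i - 1L)
      last_end <- i + 4L
    }
  }
  starts
}

# Minimal jplace v3 document builder (string), independent of write_jplace
jplace_doc <- function(tree_text, placements, fields = c("edge_num", "like_weight_ratio", "likelihood"),
                       use_nm = FALSE, version = 3) {
  p_rows <- lapply(placements, function(pl) {
    rows <- lapply(seq_along(pl$edges), function(i) {
      vals <- list(edge_num = pl$edges[i], like_weight_ratio = pl$lwr[i],
                   likelihood = if (is.null(pl$lik)) -10 else pl$lik[i])
      unname(vals[fields])
    })
    if (use_nm) list(p = rows, nm = list(list(pl$name, pl$mult %||% 1)))
    else list(p = rows, n = list(pl$name))
  })
  `%||%` <- function(a, b) if (is.null(a)) b else a
  jsonlite::toJSON(list(version = version, tree = tree_text, fields = as.list(fields),
                        placements = p_rows),
                   auto_unbox = TRUE, digits = NA)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# depth (edges from root) of a jplace edge number
edge_depth <- function(tree, edge) {
  if (is.na(edge)) return(0L)
  tree$depth[match(edge, tree$edge_num)]
}
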