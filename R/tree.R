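#' Reference tree with jplace edge numbering
#'
#' A rooted phylogeny stored edge-wise: every non-root node identifies the
#' edge above it (towards the root). Each such edge carries a branch length
#' (substitutions/site) and an integer jplace edge number, the coordinate
#' system used by placement files. Nodes are integer ids `1..n_node`.
#'
#' @section Structure:
#' A `nitro_tree` is a list with elements
#' \describe{
#'   \item{n_tip, n_node, root}{counts and the root node id}
#'   \item{parent}{integer vector, `parent[v]` is the parent of `v`
#'     (`NA` at the root)}
#'   \item{children}{list of integer child-id vectors}
#'   \item{brlen}{numeric, `brlen[v]` is the length of the edge above `v`}
#'   \item{edge_num}{integer jplace number of the edge above `v`}
#'   \item{label}{character node labels; tip labels are unique and non-empty}
#'   \item{postorder}{node ids in postorder (children before parents)}
#'   \item{depth}{integer edge-count distance from the root}
#' }
#'
#' @name nitro_tree
NULL

new_nitro_tree <- function(parent, children, brlen, edge_num, label, root) {
  n_node <- length(parent)
  tips <- which(lengths(children) == 0L)
  po <- postorder_nodes(children, root)
  depth <- integer(n_node)
  for (v in rev(po)) {
    depth[v] <- if (v == root) 0L else depth[parent[v]] + 1L
  }
  tree <- structure(
    list(
      n_tip = length(tips), n_node = n_node, root = root,
      parent = parent, children = children,
      brlen = brlen, edge_num = edge_num, label = label,
      postorder = po, depth = depth
    ),
    class = "nitro_tree"
  )
  validate_nitro_tree(tree)
}

postorder_nodes <- function(children, root) {
  n <- length(children)
  out <- integer(n)
  k <- 0L
  # iterative DFS, children visited in stored order
  stack <- list(list(node = root, i = 0L))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    kids <- children[[top$node]]
    if (top$i < length(kids)) {
      stack[[length(stack)]]$i <- top$i + 1L
      stack[[length(stack) + 1L]] <- list(node = kids[top$i + 1L], i = 0L)
    } else {
      k <- k + 1L
      out[k] <- top$node
      stack[[length(stack)]] <- NULL
    }
  }
  if (k != n) stop("tree is not connected: unreachable nodes present", call. = FALSE)
  out
}

validate_nitro_tree <- function(tree) {
  tl <- tip_labels(tree)
  if (anyDuplicated(tl)) {
    stop("duplicate tip labels: ", paste(unique(tl[duplicated(tl)]), collapse = ", "),
         call. = FALSE)
  }
  bl <- tree$brlen[-tree$root]
  if (any(!is.na(bl) & bl < 0)) stop("negative branch lengths are not allowed", call. = FALSE)
  en <- tree$edge_num[-tree$root]
  if (anyNA(en)) stop("every non-root edge needs a jplace edge number", call. = FALSE)
  if (anyDuplicated(en)) stop("duplicate jplace edge numbers", call. = FALSE)
  tree
}

#' @rdname nitro_tree
#' @param tree a `nitro_tree`
#' @export
tip_labels <- function(tree) {
  tree$label[which(lengths(tree$children) == 0L)]
}

#' @export
print.nitro_tree <- function(x, ...) {
  cat("<nitro_tree> ", x$n_tip, " tips, ", x$n_node - 1L, " edges, total length ",
      format(sum(x$brlen[-x$root], na.rm = TRUE), digits = 6), "\n", sep = "")
  invisible(x)
}

#' Parse a newick string, honoring the jplace edge-number dialect
#'
#' Reads standard newick, optionally with `{N}` edge-number annotations after
#' branch lengths (the jplace dialect). When annotations are absent, edges are
#' numbered deterministically in postorder starting at 0, so synthetic trees
#' get reproducible coordinates.
#'
#' @param text a single newick string (must end with `;`).
#' @return a [nitro_tree].
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tip_labels(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- strsplit(gsub("[[:space:]]", "", text), "")[[1]]
  if (length(s) == 0L) stop("empty newick string", call. = FALSE)
  pos <- 1L
  n_max <- sum(s %in% c("(", ",")) + 2L
  parent <- integer(0); children <- list(); brlen <- numeric(0)
  edge_num <- integer(0); label <- character(0)
  new_node <- function() {
    parent[length(parent) + 1L] <<- NA_integer_
    children[[length(children) + 1L]] <<- integer(0)
    brlen[length(brlen) + 1L] <<- NA_real_
    edge_num[length(edge_num) + 1L] <<- NA_integer_
    label[length(label) + 1L] <<- ""
    length(parent)
  }
  peek <- function() if (pos <= length(s)) s[pos] else ""
  take_label <- function() {
    start <- pos
    while (pos <= length(s) && !(s[pos] %in% c("(", ")", ",", ":", ";", "{"))) pos <<- pos + 1L
    paste(s[start:(pos - 1L)], collapse = "")
  }
  take_number <- function(what) {
    start <- pos
    while (pos <= length(s) && grepl("[0-9eE.+-]", s[pos])) pos <<- pos + 1L
    if (pos == start) stop("expected a number for ", what, " at position ", start, call. = FALSE)
    as.numeric(paste(s[start:(pos - 1L)], collapse = ""))
  }
  parse_clade <- function() {
    v <- new_node()
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        child <- parse_clade()
        parent[child] <<- v
        children[[v]] <<- c(children[[v]], child)
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        stop("unbalanced parentheses near position ", pos,
             " (token '", peek(), "')", call. = FALSE)
      }
    }
    if (!(peek() %in% c("(", ")", ",", ":", ";", "{", ""))) label[v] <<- take_label()
    if (peek() == ":") { pos <<- pos + 1L; brlen[v] <<- take_number("branch length") }
    if (peek() == "{") {
      pos <<- pos + 1L
      edge_num[v] <<- as.integer(take_number("edge number"))
      if (peek() != "}") stop("unterminated {edge number} at position ", pos, call. = FALSE)
      pos <<- pos + 1L
    }
    v
  }
  root <- parse_clade()
  if (peek() != ";") stop("expected ';' at position ", pos, " (token '", peek(), "')", call. = FALSE)
  if (length(parent) > n_max) stop("malformed newick", call. = FALSE)
  tips <- which(lengths(children) == 0L)
  if (any(label[tips] == "")) stop("unlabeled tip in newick string", call. = FALSE)
  if (any(!is.na(brlen[-root]) & brlen[-root] < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  brlen[is.na(brlen)] <- 0
  brlen[root] <- NA_real_
  have <- !is.na(edge_num[-root])
  if (all(!have)) {
    # deterministic postorder assignment, 0-based
    po <- postorder_nodes(children, root)
    po <- po[po != root]
    edge_num[po] <- seq_along(po) - 1L
  } else if (!all(have)) {
    stop("edge numbers present for some but not all edges", call. = FALSE)
  }
  new_nitro_tree(parent, children, brlen, edge_num, label, root)
}

#' Write a tree as a newick string
#'
#' @param tree a [nitro_tree].
#' @param edge_numbers include `{N}` jplace edge-number annotations.
#' @param digits significant digits for branch lengths.
#' @return a newick string ending in `;`.
#' @export
write_newick <- function(tree, edge_numbers = TRUE, digits = 10) {
  fmt <- function(v) {
    out <- tree$label[v]
    if (length(tree$children[[v]]) > 0L) {
      out <- paste0("(", paste(vapply(tree$children[[v]], fmt, ""), collapse = ","),
                    ")", tree$label[v])
    }
    if (v != tree$root) {
      out <- paste0(out, ":", format(tree$brlen[v], digits = digits, scientific = FALSE))
      if (edge_numbers) out <- paste0(out, "{", tree$edge_num[v], "}")
    }
    out
  }
  paste0(fmt(tree$root), ";")
}

#' Convert between nitro_tree and ape's phylo
#'
#' `as_nitro_tree()` adopts ape node ids unchanged and assigns postorder
#' 0-based jplace edge numbers; `as_phylo()` goes the other way (edge numbers
#' are dropped, ape has no slot for them).
#'
#' @param phy an `ape::phylo` (rooted).
#' @return a [nitro_tree] / an `ape::phylo`.
#' @export
as_nitro_tree <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  n_node <- ape::Ntip(phy) + phy$Nnode
  parent <- rep(NA_integer_, n_node)
  children <- rep(list(integer(0)), n_node)
  brlen <- rep(NA_real_, n_node)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]; v <- phy$edge[i, 2]
    parent[v] <- p
    children[[p]] <- c(children[[p]], v)
    brlen[v] <- if (is.null(phy$edge.length)) 0 else phy$edge.length[i]
  }
  root <- which(is.na(parent) & lengths(children) > 0L)
  label <- character(n_node)
  label[seq_len(ape::Ntip(phy))] <- phy$tip.label
  edge_num <- rep(NA_integer_, n_node)
  po <- postorder_nodes(children, root)
  po <- po[po != root]
  edge_num[po] <- seq_along(po) - 1L
  new_nitro_tree(parent, children, brlen, edge_num, label, root)
}

#' @rdname as_nitro_tree
#' @param tree a [nitro_tree].
#' @export
as_phylo <- function(tree) {
  ape::read.tree(text = write_newick(tree, edge_numbers = FALSE))
}

# node id carrying a given jplace edge number (vectorized); errors on unknown
edge_node <- function(tree, edge_num) {
  idx <- match(edge_num, tree$edge_num)
  if (anyNA(idx)) {
    stop("edge number(s) not in tree: ",
         paste(edge_num[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

# all nodes in the clade rooted at v (including v)
clade_nodes <- function(tree, v) {
  out <- integer(0)
  queue <- v
  while (length(queue) > 0L) {
    x <- queue[1L]; queue <- queue[-1L]
    out <- c(out, x)
    queue <- c(queue, tree$children[[x]])
  }
  out
}

# most recent common ancestor of a set of nodes
mrca_node <- function(tree, nodes) {
  if (length(nodes) == 1L) return(nodes)
  anc <- function(v) {
    path <- v
    while (!is.na(tree$parent[v])) { v <- tree$parent[v]; path <- c(path, v) }
    path
  }
  common <- Reduce(intersect, lapply(nodes, anc))
  common[which.max(tree$depth[common])]
}
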