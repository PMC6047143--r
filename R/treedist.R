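#' Parse a Newick tree
#'
#' Thin wrapper around [ape::read.tree()] accepting a string or a file.
#' Rooted input is accepted and treated as unrooted by all distance
#' computations.
#'
#' @param x Newick text (containing `(`) or a file path.
#' @return an [ape::phylo] tree.
#' @export
parse_newick <- function(x) {
  tr <- if (grepl("(", x, fixed = TRUE)) ape::read.tree(text = x)
        else ape::read.tree(x)
  if (is.null(tr)) stop("failed to parse Newick input")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels in tree")
  tr
}

# Non-trivial bipartitions of an unrooted tree, as canonical keys.
# Each split is the tip set of an internal edge; canonicalized to the side
# containing the alphabetically smallest leaf, key = sorted labels joined.
tree_splits <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  tree <- ape::unroot(tree)
  nn <- max(tree$edge)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  below <- vector("list", nn)
  for (i in seq_len(n)) below[[i]] <- tree$tip.label[i]
  internal <- sort(unique(tree$edge[, 1L]), decreasing = TRUE)
  repeat {
    done <- TRUE
    for (v in internal) {
      if (!is.null(below[[v]])) next
      ch <- kids[[as.character(v)]]
      if (all(!vapply(below[ch], is.null, logical(1L)))) {
        below[[v]] <- unlist(below[ch], use.names = FALSE)
      } else done <- FALSE
    }
    if (done) break
  }
  anchor <- min(tips)
  keys <- character()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    if (child <= n) next                      # trivial split
    side <- below[[child]]
    if (length(side) < 2L || length(side) > n - 2L) next
    if (!anchor %in% side) side <- setdiff(tips, side)
    keys <- c(keys, paste(sort(side), collapse = "\r"))
  }
  unique(keys)
}

#' Robinson-Foulds distance
#'
#' The number of non-trivial bipartitions present in exactly one of the two
#' unrooted trees (symmetric difference of split sets).
#'
#' @param t1,t2 [ape::phylo] trees over the same leaf set.
#' @return integer distance.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Normalized Robinson-Foulds distance
#'
#' `d_RF / (2n - 6)`: the distance divided by its maximum between two fully
#' resolved unrooted n-leaf trees.
#'
#' @param d_rf integer RF distance.
#' @param n leaf count (>= 4).
#' @export
normalized_rf <- function(d_rf, n) {
  if (n < 4L) stop("normalized RF requires n >= 4")
  d_rf / (2 * n - 6)
}

# topology of quadruple q (indices into tips) under split membership matrix:
# returns 0 (unresolved) or 1/2/3 for ab|cd, ac|bd, ad|bc
quartet_topology <- function(memb, q) {
  if (nrow(memb) == 0L) return(0L)
  sub <- memb[, q, drop = FALSE]
  rs <- rowSums(sub)
  cand <- which(rs == 2L)
  for (k in cand) {
    v <- sub[k, ]
    if (v[1L] && v[2L]) return(1L)
    if (v[1L] && v[3L]) return(2L)
    if (v[1L] && v[4L]) return(3L)
    # first element on the other side: complement pairing
    if (v[2L] && v[3L]) return(3L)
    if (v[2L] && v[4L]) return(2L)
    if (v[3L] && v[4L]) return(1L)
  }
  0L
}

split_membership <- function(tree, tips) {
  keys <- tree_splits(tree)
  memb <- matrix(FALSE, nrow = length(keys), ncol = length(tips),
                 dimnames = list(NULL, tips))
  for (i in seq_along(keys))
    memb[i, strsplit(keys[i], "\r", fixed = TRUE)[[1L]]] <- TRUE
  memb
}

#' Quartet distance
#'
#' The number of 4-leaf subsets whose induced quartet topologies differ
#' between the two trees, by direct enumeration of all `choose(n, 4)`
#' quadruples (intended for n up to ~40). With
#' `count_unresolved = TRUE` (default) a quartet resolved in one tree but
#' unresolved in the other counts as a difference; for fully resolved trees
#' the flag is irrelevant.
#'
#' @param t1,t2 [ape::phylo] trees over the same leaf set, n >= 4.
#' @param count_unresolved count resolved-vs-unresolved as different?
#' @return integer distance.
#' @export
quartet_distance <- function(t1, t2, count_unresolved = TRUE) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  tips <- sort(t1$tip.label)
  n <- length(tips)
  if (n < 4L) stop("quartet distance requires n >= 4")
  m1 <- split_membership(t1, tips)
  m2 <- split_membership(t2, tips)
  quads <- utils::combn(n, 4L)
  d <- 0L
  for (k in seq_len(ncol(quads))) {
    q <- quads[, k]
    a <- quartet_topology(m1, q)
    b <- quartet_topology(m2, q)
    if (a != b && (count_unresolved || (a != 0L && b != 0L))) d <- d + 1L
  }
  d
}

#' Normalized quartet distance
#'
#' `d_Q / choose(n, 4)`.
#'
#' @param d_q integer quartet distance.
#' @param n leaf count (>= 4).
#' @export
normalized_quartet <- function(d_q, n) {
  if (n < 4L) stop("normalized quartet distance requires n >= 4")
  d_q / choose(n, 4)
}

#' Test splids (or any splits) for compatibility with a tree
#'
#' A splid's presence/absence partition, restricted to its non-missing taxa
#' that are leaves of the tree, is compatible with the tree when it equals
#' some branch-induced bipartition restricted to the same taxa, or is
#' trivial after restriction (fewer than two taxa on either side).
#'
#' @param splids list of `splid` objects (or any objects with `presence`,
#'   `absence` fields).
#' @param tree an [ape::phylo] tree.
#' @return list with `compatible` (logical per splid) and `fraction`.
#' @export
splits_compatible_with_tree <- function(splids, tree) {
  tips <- tree$tip.label
  keys <- tree_splits(tree)
  sides <- lapply(keys, function(k) strsplit(k, "\r", fixed = TRUE)[[1L]])
  comp <- vapply(splids, function(sp) {
    pres <- intersect(sp$presence, tips)
    abs_ <- intersect(sp$absence, tips)
    if (length(pres) < 2L || length(abs_) < 2L) return(TRUE)  # trivial
    scope <- c(pres, abs_)
    key_p <- paste(sort(pres), collapse = "\r")
    key_a <- paste(sort(abs_), collapse = "\r")
    for (s in sides) {
      r <- intersect(s, scope)
      k <- paste(sort(r), collapse = "\r")
      if (k == key_p || k == key_a) return(TRUE)
    }
    FALSE
  }, logical(1L))
  list(compatible = comp, fraction = if (length(comp)) mean(comp) else NaN)
}

#' Rescale a tree to a target root-to-tip height
#'
#' Multiplies every branch length by `target_height / h`, where `h` is the
#' maximum root-to-tip path length of the (rooted) input.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param target_height desired maximum root-to-tip distance.
#' @export
rescale_tree <- function(tree, target_height) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  h <- max(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
  if (h <= 0) stop("tree height is zero; cannot rescale")
  tree$edge.length <- tree$edge.length * (target_height / h)
  tree
}
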