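#' Neighbor joining from a labeled distance matrix
#'
#' The canonical agglomerative algorithm on the Q-criterion
#' \eqn{Q_{ij} = (r-2) d_{ij} - R_i - R_j} (with \eqn{R_i = \sum_k d_{ik}}
#' over the r active nodes): the pair minimizing Q is joined, branch lengths
#' are \eqn{v_i = d_{ij}/2 + (R_i - R_j)/(2(r-2))}, \eqn{v_j = d_{ij} - v_i},
#' and distances to the new node are \eqn{(d_{ik}+d_{jk}-d_{ij})/2}.
#' For reproducibility the matrix is first sorted by label, Q-ties are broken
#' by the lexicographically smallest label pair (clusters are keyed by their
#' smallest leaf), and negative branch lengths are clamped to zero with the
#' total deficit reported in the `"clamped"` attribute. Consistent on
#' additive matrices: exact path-length input returns the generating
#' topology and branch lengths.
#'
#' @param m symmetric labeled distance matrix, n >= 3, finite entries.
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(m) {
  if (any(is.na(m))) stop("distance matrix contains NA/NaN")
  m <- check_distance_matrix(m, tol = 1e-8)
  n <- nrow(m)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  ord <- order(rownames(m))
  D <- m[ord, ord]
  # each active node: newick fragment + key (smallest leaf label in cluster)
  frag <- rownames(D)
  key <- rownames(D)
  clamped <- 0
  clamp <- function(v) {
    if (v < 0) { clamped <<- clamped - v; 0 } else v
  }
  fmt <- function(v) sprintf("%.15g", v)
  while (length(key) > 3) {
    r <- length(key)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q == qmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_keys <- apply(cand, 1, function(ij) {
      ks <- sort(c(key[ij[1]], key[ij[2]]))
      paste(ks, collapse = "\r")
    })
    pick <- cand[order(pair_keys)[1], ]
    i <- pick[1]; j <- pick[2]
    vi <- clamp(D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2)))
    vj <- clamp(D[i, j] - (D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))))
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(vi), frag[j], fmt(vj))
    newkey <- min(key[i], key[j])
    dnew <- (D[i, -c(i, j)] + D[j, -c(i, j)] - D[i, j]) / 2
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, dnew), c(dnew, 0))
    frag <- c(frag[-c(i, j)], newfrag)
    key <- c(key[-c(i, j)], newkey)
  }
  va <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  vb <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  vc <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], fmt(va), frag[2], fmt(vb), frag[3], fmt(vc))
  tr <- ape::read.tree(text = nwk)
  if (clamped > 0) {
    message(sprintf("clamped negative NJ branch lengths (total deficit %.6g)", clamped))
  }
  attr(tr, "clamped") <- clamped
  tr
}

#' Root a tree on the pendant edge of an outgroup leaf
#'
#' The root is placed at the midpoint of the outgroup's pendant edge; the
#' set of non-trivial bipartitions is unchanged by rooting.
#'
#' @param tree a `phylo`.
#' @param outgroup leaf label.
#' @return a rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  tip <- match(outgroup, tree$tip.label)
  if (is.na(tip)) stop(sprintf("outgroup '%s' is not a leaf of the tree", outgroup))
  e <- which(tree$edge[, 2] == tip)
  phytools::reroot(tree, tip, position = tree$edge.length[e] / 2)
}

#' Non-trivial bipartitions of a tree
#'
#' One bipartition (split) per internal edge, each with both blocks of size
#' >= 2; an unrooted binary tree on n leaves yields n - 3. Splits are
#' canonicalized so the block containing the lexicographically smallest leaf
#' comes first; the two child edges of a root node induce the same split and
#' are deduplicated.
#'
#' @param tree a `phylo` (rooted or unrooted).
#' @return object of class `bipartition_set`: list with `splits` (list of
#'   two-block lists), `keys` (canonical strings) and `labels`.
#' @export
bipartition_set <- function(tree) {
  tips <- tree$tip.label
  ntip <- length(tips)
  tr <- stats::reorder(tree, "postorder")
  desc <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tips[i]
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    desc[[par]] <- c(desc[[par]], desc[[child]])
  }
  anchor <- min(tips)
  keys <- character(0)
  splits <- list()
  internal_children <- tr$edge[tr$edge[, 2] > ntip, 2]
  for (node in internal_children) {
    inside <- sort(desc[[node]])
    outside <- sort(setdiff(tips, inside))
    if (length(inside) < 2 || length(outside) < 2) next
    blocks <- if (anchor %in% inside) list(inside, outside) else list(outside, inside)
    k <- paste(blocks[[1]], collapse = "\r")
    if (!k %in% keys) {
      keys <- c(keys, k)
      splits[[length(splits) + 1]] <- blocks
    }
  }
  structure(list(splits = splits, keys = keys, labels = sort(tips)),
            class = "bipartition_set")
}

#' @export
print.bipartition_set <- function(x, ...) {
  cat(sprintf("<bipartition_set> %d non-trivial splits over %d leaves\n",
              length(x$keys), length(x$labels)))
  invisible(x)
}

#' Penny--Hendy (Robinson--Foulds) topology distance
#'
#' The size of the symmetric difference between the two trees' non-trivial
#' bipartition sets; for binary trees this equals twice the number of
#' internal branches defining different bipartitions of the tips. Zero for
#' identical topologies regardless of branch lengths; always even for binary
#' trees; bounded by 2(n - 3).
#'
#' @param t1,t2 `phylo` trees on identical leaf sets.
#' @return nonnegative integer.
#' @export
tree_topology_distance <- function(t1, t2) {
  b1 <- bipartition_set(t1)
  b2 <- bipartition_set(t2)
  if (!identical(b1$labels, b2$labels)) stop("trees have different leaf sets")
  length(setdiff(b1$keys, b2$keys)) + length(setdiff(b2$keys, b1$keys))
}

#' Parse / write newick
#'
#' Thin validated wrappers around ape. `parse_newick` reports the position
#' of the first unbalanced parenthesis; trees without branch lengths keep
#' them absent (not zero). `write_newick` serializes with enough digits that
#' parse(write(t)) reproduces topology exactly and lengths to 1e-9.
#'
#' @param s a newick string.
#' @return for `parse_newick` a `phylo`; for `write_newick` a string.
#' @export
parse_newick <- function(s) {
  depth <- 0
  chars <- strsplit(s, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1
    if (chars[i] == ")") depth <- depth - 1
    if (depth < 0) stop(sprintf("unbalanced ')' at position %d", i))
  }
  if (depth != 0) stop(sprintf("unbalanced '(': %d unclosed at end of string", depth))
  tr <- ape::read.tree(text = s)
  if (is.null(tr)) stop("newick string could not be parsed")
  tr
}

#' @rdname parse_newick
#' @param tree a `phylo`.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree, digits = 12)
}
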