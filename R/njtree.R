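#' Neighbor-joining tree from a distance matrix
#'
#' Classic NJ agglomeration, exact on additive distance matrices.  Ties in the
#' Q criterion are broken deterministically by the lexicographically smallest
#' pair of cluster representatives (each cluster is represented by its
#' smallest leaf label).  Negative branch lengths are clamped to zero with the
#' deficit moved to the sibling branch, preserving the path length between the
#' joined clusters.
#'
#' @param d symmetric distance matrix with labels (>= 3 taxa).
#' @return unrooted \code{ape} phylo tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  labels <- rownames(d)
  if (is.null(labels)) stop("distance matrix must be labelled")
  n <- nrow(d)
  if (n < 3) stop("need at least 3 taxa")
  if (any(d < 0)) stop("distances must be non-negative")

  newick <- labels          # growing subtree strings
  repname <- labels         # smallest leaf label per cluster, for tie-breaks
  D <- d
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      p <- sort(c(repname[ij[1]], repname[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    nwk <- sprintf("(%s:%s,%s:%s)", newick[i], format(li, digits = 15),
                   newick[j], format(lj, digits = 15))
    dn <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keepidx <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keepidx, keepidx, drop = FALSE], dn[keepidx]),
                c(dn[keepidx], 0))
    newick <- c(newick[keepidx], nwk)
    repname <- c(repname[keepidx], min(repname[c(i, j)]))
    D <- D2
  }
  # final three-point resolution
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  l1 <- max(l1, 0); l2 <- max(l2, 0); l3 <- max(l3, 0)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 newick[1], format(l1, digits = 15),
                 newick[2], format(l2, digits = 15),
                 newick[3], format(l3, digits = 15))
  ape::read.tree(text = txt)
}

# canonical bipartition keys for the internal edges of an unrooted tree:
# each key is the sorted leaf set on the side NOT containing the
# alphabetically first leaf, collapsed with "|"; value = child node id
tree_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1]
  internal <- tree$edge[, 2][tree$edge[, 2] > ntip]
  out <- list()
  for (child in internal) {
    tips <- tree$tip.label[leaf_descendants(tree, child)]
    side <- if (anchor %in% tips) setdiff(tree$tip.label, tips) else tips
    if (length(side) < 2 || length(side) > ntip - 2) next  # trivial split
    out[[paste(sort(side), collapse = "|")]] <- child
  }
  out
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples the kept alignment columns with replacement, rebuilds the NJ tree
#' for each replicate and reports, for every internal split of the full-data
#' tree, the fraction of replicate trees that contain it.  Supports are stored
#' as node labels of the returned tree (ape convention) and in the
#' \code{support} attribute keyed by split.
#'
#' @param x \code{msa}.
#' @param selection \code{block_selection}.
#' @param n_replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed; identical seeds give identical supports.
#' @param correction distance correction passed to \code{\link{block_distance}}.
#' @return the full-data NJ phylo tree with per-internal-node support in
#'   \code{[0, 1]} as \code{node.label} (root label empty).
#' @export
bootstrap_support <- function(x, selection, n_replicates = 100, seed = 1,
                              correction = "poisson") {
  stopifnot(n_replicates >= 1)
  cols <- selection$kept_columns
  if (!length(cols)) stop("no kept columns")
  full <- nj_tree(block_distance(x, selection, correction))
  splits <- tree_splits(full)
  hits <- setNames(numeric(length(splits)), names(splits))
  set.seed(as.integer(seed))
  for (b in seq_len(n_replicates)) {
    rcols <- sample(cols, length(cols), replace = TRUE)
    rep_tree <- nj_tree(block_distance(x, rcols, correction))
    rep_splits <- names(tree_splits(rep_tree))
    hits[names(splits) %in% rep_splits] <- hits[names(splits) %in% rep_splits] + 1
  }
  support <- hits / n_replicates
  ntip <- length(full$tip.label)
  labs <- rep("", full$Nnode)
  for (k in names(splits)) labs[splits[[k]] - ntip] <- format(support[k], digits = 6)
  full$node.label <- labs
  attr(full, "support") <- support
  full
}

#' Check orthogroup monophyly on a leaf-labelled tree
#'
#' An orthogroup is consistent iff its leaves form a clade on the unrooted
#' tree, i.e. some edge separates exactly that leaf set.  Singleton
#' orthogroups (and one spanning all leaves) are trivially consistent.  For
#' split orthogroups, the offending leaves are those outside (or foreign
#' inside) the best-matching side, the side maximizing members minus
#' intruders, preferring fewer intruders on ties.
#'
#' @param tree phylo tree.
#' @param labels named character vector mapping every leaf to its orthogroup.
#' @return data.frame (og_id, consistent, offending).
#' @export
check_og_monophyly <- function(tree, labels) {
  unlabeled <- setdiff(tree$tip.label, names(labels))
  if (length(unlabeled)) stop("unlabeled leaves: ", paste(unlabeled, collapse = ", "))
  tips <- tree$tip.label
  ntip <- length(tips)
  # all bipartition sides: each internal edge contributes both sides, plus
  # singleton tip sides
  sides <- lapply(tips, function(t) t)
  for (child in tree$edge[, 2][tree$edge[, 2] > ntip]) {
    tp <- tips[leaf_descendants(tree, child)]
    sides <- c(sides, list(tp), list(setdiff(tips, tp)))
  }
  side_keys <- vapply(sides, function(s) paste(sort(s), collapse = "|"), "")
  out <- lapply(sort(unique(labels[tips])), function(og) {
    members <- sort(tips[labels[tips] == og])
    if (length(members) <= 1 || length(members) == ntip)
      return(data.frame(og_id = og, consistent = TRUE, offending = "",
                        stringsAsFactors = FALSE))
    key <- paste(members, collapse = "|")
    if (key %in% side_keys)
      return(data.frame(og_id = og, consistent = TRUE, offending = "",
                        stringsAsFactors = FALSE))
    score <- vapply(sides, function(s)
      length(intersect(s, members)) - length(setdiff(s, members)), 0)
    intruders <- vapply(sides, function(s) length(setdiff(s, members)), 0)
    best <- order(-score, intruders, side_keys)[1]
    off <- sort(union(setdiff(members, sides[[best]]),
                      setdiff(sides[[best]], members)))
    data.frame(og_id = og, consistent = FALSE,
               offending = paste(off, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Leave-one-out probe for long-branch attraction
#'
#' Builds the tree for an orthogroup's alignment, removes the longest-branch
#' leaf other than the focal gene (its suspected attractor), rebuilds, and
#' flags long-branch attraction when the focal gene's sister group changes
#' between the two trees.
#'
#' @param x \code{msa} of the orthogroup (>= 5 sequences, so that the reduced
#'   tree still has >= 4).
#' @param focal_id leaf to probe.
#' @param correction distance correction.
#' @param ... parameters forwarded to \code{\link{select_blocks}}.
#' @return list of class \code{lba_report}: placement_full,
#'   placement_without_partner (sister leaf sets), removed_partner, lba_flag.
#' @export
lba_probe <- function(x, focal_id, correction = "poisson", ...) {
  stopifnot(inherits(x, "msa"))
  if (!focal_id %in% x$ids) stop("focal gene not present: ", focal_id)
  if (length(x$ids) < 4) stop("need at least 4 taxa")
  sel <- select_blocks(x, ...)
  full <- nj_tree(block_distance(x, sel, correction))
  # longest terminal branch among the non-focal leaves
  ntip <- length(full$tip.label)
  tip_edges <- which(full$edge[, 2] <= ntip)
  tip_len <- setNames(full$edge.length[tip_edges], full$tip.label[full$edge[tip_edges, 2]])
  tip_len <- tip_len[names(tip_len) != focal_id]
  partner <- names(tip_len)[order(-tip_len, names(tip_len))[1]]
  keep <- x$ids != partner
  if (sum(keep) < 4) stop("removal would leave fewer than 4 taxa")
  x2 <- msa(x$ids[keep], x$rows[keep])
  sel2 <- select_blocks(x2, ...)
  reduced <- nj_tree(block_distance(x2, sel2, correction))
  s_full <- setdiff(sister_leaves(full, focal_id), partner)
  s_red <- sister_leaves(reduced, focal_id)
  structure(list(placement_full = s_full,
                 placement_without_partner = s_red,
                 removed_partner = partner,
                 lba_flag = !setequal(s_full, s_red)),
            class = "lba_report")
}

#' @export
print.lba_report <- function(x, ...) {
  cat("LBA probe: removed", x$removed_partner, "->",
      if (x$lba_flag) "placement CHANGED (LBA suspected)" else "placement stable", "\n")
  cat("  sister with partner   :", paste(x$placement_full, collapse = ", "), "\n")
  cat("  sister without partner:", paste(x$placement_without_partner, collapse = ", "), "\n")
  invisible(x)
}

# sister group of a leaf on an unrooted tree: leaf set of the smallest
# component adjacent to the leaf's attachment node (focal excluded);
# deterministic tie-break by sorted labels
sister_leaves <- function(tree, leaf) {
  ntip <- length(tree$tip.label)
  tipno <- match(leaf, tree$tip.label)
  v <- tree$edge[tree$edge[, 2] == tipno, 1]
  nbr <- c(tree$edge[tree$edge[, 1] == v, 2], tree$edge[tree$edge[, 2] == v, 1])
  nbr <- setdiff(nbr, tipno)
  comps <- lapply(nbr, function(u) {
    if (u <= ntip) return(tree$tip.label[u])
    if (u %in% tree$edge[tree$edge[, 1] == v, 2]) {
      sort(tree$tip.label[leaf_descendants(tree, u)])
    } else {
      # the component through the parent side of v
      below_v <- leaf_descendants(tree, v)
      sort(setdiff(tree$tip.label, tree$tip.label[below_v]))
    }
  })
  comps <- comps[order(vapply(comps, length, 0L),
                       vapply(comps, function(s) paste(s, collapse = "|"), ""))]
  comps[[1]]
}
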