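#' Subfamily label of an OG id
#'
#' Strips an optional \code{OG-} prefix and a trailing hyphen-numeral suffix
#' (Arabic or Roman, e.g. \code{-1}, \code{-II}) from orthogroup labels:
#' OGs of a multi-OG subfamily are differentiated by such suffixes, while
#' singleton subfamilies carry the bare name.
#'
#' @param og_id character vector of OG labels.
#' @return character vector of subfamily labels.
#' @export
og_subfamily_label <- function(og_id) {
  x <- sub("^OG-", "", og_id)
  sub("-(?:[0-9]+|[IVX]+)$", "", x, perl = TRUE)
}

#' Pick one representative gene per orthogroup
#'
#' The representative is the member with the smallest mean distance to the
#' other members of its orthogroup (ties broken by id); singletons represent
#' themselves.
#'
#' @param d distance matrix over genes.
#' @param og_map named vector gene id -> og id.
#' @return named character vector og id -> representative gene id.
#' @export
pick_representatives <- function(d, og_map) {
  ogs <- sort(unique(og_map))
  out <- vapply(ogs, function(og) {
    members <- sort(names(og_map)[og_map == og])
    if (length(members) == 1) return(members)
    miss <- setdiff(members, rownames(d))
    if (length(miss)) stop("representative candidates missing from distances: ",
                           paste(miss, collapse = ", "))
    mean_d <- vapply(members, function(m) mean(d[m, setdiff(members, m)]), 0)
    members[order(mean_d, members)[1]]
  }, "")
  setNames(out, ogs)
}

#' Group orthogroups into subfamilies from a representative tree
#'
#' On a support-annotated tree with one representative leaf per OG, the
#' maximal clades whose split support reaches \code{support_min} and whose
#' within-clade leaf-path diameter is at most \code{depth_max} become multi-OG
#' subfamilies; every remaining OG is its own singleton subfamily.
#'
#' @param og_tree phylo tree over OG representatives with bootstrap supports as
#'   node labels (see \code{\link{bootstrap_support}}); leaves must be named by
#'   OG (or be mapped via \code{leaf_og}).
#' @param support_min minimum split support in [0, 1].
#' @param depth_max maximum within-clade path diameter; default the 75th
#'   percentile of pairwise representative distances on the tree.
#' @param leaf_og optional named vector leaf -> og id.
#' @return list of class \code{subfamily_map}: \code{og_to_subfamily} (named
#'   vector), \code{members} (list per subfamily), and the thresholds used.
#' @export
group_subfamilies <- function(og_tree, support_min = 0.9, depth_max = NULL,
                              leaf_og = NULL) {
  tips <- og_tree$tip.label
  if (is.null(leaf_og)) leaf_og <- setNames(tips, tips)
  miss <- setdiff(tips, names(leaf_og))
  if (length(miss)) stop("representative missing OG mapping: ",
                         paste(miss, collapse = ", "))
  pd <- ape::cophenetic.phylo(og_tree)
  if (is.null(depth_max))
    depth_max <- unname(quantile(pd[upper.tri(pd)], 0.75))
  ntip <- length(tips)
  splits <- tree_splits(og_tree)
  labs <- og_tree$node.label
  cands <- list()
  for (key in names(splits)) {
    child <- splits[[key]]
    sup <- suppressWarnings(as.numeric(labs[child - ntip]))
    if (is.na(sup) || sup < support_min) next
    side <- strsplit(key, "|", fixed = TRUE)[[1]]
    for (grp in list(side, setdiff(tips, side))) {
      if (length(grp) < 2 || length(grp) > ntip - 1) next
      diam <- max(pd[grp, grp])
      if (diam <= depth_max)
        cands[[length(cands) + 1]] <- sort(grp)
    }
  }
  # maximal, non-overlapping clades, largest first
  cands <- unique(cands)
  cands <- cands[order(-vapply(cands, length, 0L),
                       vapply(cands, function(g) g[1], ""))]
  taken <- character(0)
  groups <- list()
  for (g in cands) {
    if (!length(intersect(g, taken))) {
      groups[[length(groups) + 1]] <- g
      taken <- c(taken, g)
    }
  }
  for (t in setdiff(tips, taken)) groups[[length(groups) + 1]] <- t
  og_to_sub <- character(0)
  members <- list()
  for (k in seq_along(groups)) {
    ogs <- sort(unname(leaf_og[groups[[k]]]))
    sub_id <- sprintf("SF_%02d", k)
    og_to_sub[ogs] <- sub_id
    members[[sub_id]] <- ogs
  }
  structure(list(og_to_subfamily = og_to_sub, members = members,
                 support_min = support_min, depth_max = depth_max),
            class = "subfamily_map")
}

#' @export
print.subfamily_map <- function(x, ...) {
  n_multi <- sum(vapply(x$members, length, 0L) >= 2)
  cat("subfamily_map:", length(x$members), "subfamilies over",
      length(x$og_to_subfamily), "OGs (", n_multi, "multi-OG )\n")
  invisible(x)
}

#' Apply the naming convention to a subfamily map
#'
#' Singleton subfamilies name their OG with the bare base label
#' (\code{OG-<base>}); multi-OG subfamilies differentiate their OGs by a
#' hyphen and a number (\code{OG-<base>-1}, \code{-2}, ...), ordered by
#' descending member count, ties by lexicographically smallest member id.  A
#' \code{rank} column in \code{seed_names} can pin explicit numbers so a
#' published labelling is reproduced exactly.
#'
#' @param map \code{subfamily_map}.
#' @param seed_names data.frame (subfamily, base) giving each subfamily its
#'   literature base label; optional columns og_id and rank pin numbers.
#' @param og_sizes optional named vector og id -> member count used for the
#'   default ordering (singletons assumed when missing).
#' @param og_min_member optional named vector og id -> smallest member id.
#' @return data.frame (og_id, subfamily, name, rank).
#' @export
assign_names <- function(map, seed_names, og_sizes = NULL, og_min_member = NULL) {
  sub_base <- unique(seed_names[, c("subfamily", "base")])
  if (anyDuplicated(sub_base$base)) stop("duplicate base labels in seed_names")
  miss <- setdiff(names(map$members), seed_names$subfamily)
  if (length(miss)) stop("seed_names missing subfamilies: ",
                         paste(miss, collapse = ", "))
  out <- list()
  for (sub in names(map$members)) {
    ogs <- map$members[[sub]]
    base <- seed_names$base[match(sub, seed_names$subfamily)]
    if (length(ogs) == 1) {
      out[[length(out) + 1]] <- data.frame(og_id = ogs, subfamily = base,
                                           name = paste0("OG-", base),
                                           rank = NA_integer_,
                                           stringsAsFactors = FALSE)
      next
    }
    rank <- rep(NA_integer_, length(ogs))
    if (all(c("og_id", "rank") %in% names(seed_names))) {
      pin <- seed_names[!is.na(seed_names$og_id) & seed_names$og_id %in% ogs, ]
      rank[match(pin$og_id, ogs)] <- pin$rank
    }
    open <- which(is.na(rank))
    if (length(open)) {
      sizes <- if (is.null(og_sizes)) rep(1, length(open)) else
        og_sizes[ogs[open]]
      minmem <- if (is.null(og_min_member)) ogs[open] else og_min_member[ogs[open]]
      o <- order(-sizes, minmem)
      rank[open[o]] <- setdiff(seq_along(ogs), rank[!is.na(rank)])
    }
    out[[length(out) + 1]] <- data.frame(og_id = ogs, subfamily = base,
                                         name = paste0("OG-", base, "-", rank),
                                         rank = rank, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res[order(res$subfamily, res$rank, res$og_id), ]
}
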