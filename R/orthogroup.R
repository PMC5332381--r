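#' Reciprocal best hit pairs
#'
#' A cross-species pair (a, b) is kept iff b is a's top-scoring hit among the
#' genes of b's species and a is b's top hit among the genes of a's species —
#' the classic operational evidence of orthology.  Ties in score are broken by
#' ascending gene id, matching the hit-ranking contract.
#'
#' @param hits \code{\link{hit_table}}.
#' @param include character vector of gene ids eligible for pairing (default
#'   all).
#' @return data.frame (a, b) of unordered pairs, a < b.
#' @export
reciprocal_best_pairs <- function(hits, include = hits$id) {
  stopifnot(inherits(hits, "hit_table"))
  ids <- hits$id
  keep <- ids %in% include
  best <- best_hit_per_species(hits, keep)
  pairs <- list()
  for (a in ids[keep]) {
    ba <- best[[a]]
    for (s in names(ba)) {
      b <- ba[[s]]
      if (a < b) {
        bb <- best[[b]]
        sa <- hits$species[match(a, ids)]
        if (!is.null(bb) && !is.na(bb[sa]) && bb[sa] == a)
          pairs[[length(pairs) + 1]] <- c(a, b)
      }
    }
  }
  if (!length(pairs))
    return(data.frame(a = character(0), b = character(0), stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, pairs))
  data.frame(a = out[, 1], b = out[, 2], stringsAsFactors = FALSE)
}

# per gene: named vector (species -> best target id in that species),
# restricted to eligible genes; ties broken by ascending id
best_hit_per_species <- function(hits, keep) {
  ids <- hits$id
  species <- hits$species
  out <- vector("list", length(ids))
  names(out) <- ids
  sp_idx <- split(which(keep), species[keep])
  for (qi in which(keep)) {
    q <- ids[qi]
    res <- character(0)
    for (s in names(sp_idx)) {
      if (s == species[qi]) next
      cand <- sp_idx[[s]]
      sc <- hits$scores[qi, cand]
      o <- order(-sc, ids[cand])
      res[s] <- ids[cand[o[1]]]
    }
    out[[qi]] <- res
  }
  out
}

simple_components <- function(nodes, edges) {
  parent <- setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      ra <- find(match(edges$a[k], nodes))
      rb <- find(match(edges$b[k], nodes))
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_along(nodes), find, 0L)
  split(nodes, roots)
}

#' Build orthogroups anchored at the monocot/dicot split
#'
#' Orthogroup cores are the connected components of the reciprocal-best-hit
#' graph over valid-status genes of the non-basal species.  Each still
#' unplaced non-basal gene then joins the orthogroup of its top cross-species
#' hit when that hit scores at least \code{in_paralog_ratio} times the core's
#' median intra-core cross-species score (in-paralog absorption).  Genes of the
#' basal outgroup never seed cores: they attach to the orthogroup of their top
#' non-basal hit when at least one member of that orthogroup reciprocates
#' (i.e. has the basal gene as its best hit in the basal species); otherwise
#' they stay unassigned.  Pseudogene/remnant records are excluded from cores
#' but are attached by the in-paralog rule, so downstream matrices can flag
#' them.  A manual-overrides table (gene, og_id) is honoured last, letting a
#' published curation be reproduced exactly.
#'
#' @param records \code{protein_records}.
#' @param hits \code{\link{hit_table}} over the records.
#' @param registry \code{species_registry} (must flag the basal outgroup).
#' @param tax optional \code{taxonomy}; when given the anchor clades must
#'   resolve in it.
#' @param anchor names of the two clades defining the reference split.
#' @param in_paralog_ratio score ratio for in-paralog absorption.
#' @param manual_overrides optional data.frame (id, og_id).
#' @return list of class \code{orthogroup_set} with elements \code{og_ids},
#'   \code{assignments} (id, species, og_id, provenance), \code{unassigned}
#'   and \code{outgroup_specific}.
#' @export
build_orthogroups <- function(records, hits, registry, tax = NULL,
                              anchor = c("monocots", "dicots"),
                              in_paralog_ratio = 0.8, manual_overrides = NULL) {
  if (nrow(records) == 0) stop("empty record set")
  if (!is.null(tax)) {
    missing_anchor <- setdiff(anchor, names(tax$clades))
    if (length(missing_anchor))
      stop("anchor split absent from taxonomy: ", paste(missing_anchor, collapse = ", "))
  }
  basal <- basal_species(registry)
  lin <- registry$lineage[match(records$species, registry$code)]
  covered <- unique(lin[records$status == "valid"])
  if (!all(c("monocot", "dicot") %in% covered))
    stop("records must cover both sides of the anchor split")

  core_ids <- records$id[records$status == "valid" & records$species != basal]
  rbh <- reciprocal_best_pairs(hits, include = core_ids)
  comps <- simple_components(core_ids, rbh)
  comps <- comps[vapply(comps, length, 0L) >= 2]  # singletons handled below

  assign <- setNames(rep(NA_character_, nrow(records)), records$id)
  prov <- setNames(rep(NA_character_, nrow(records)), records$id)
  tmp_labels <- sprintf("tmp%04d", seq_along(comps))
  core_median <- numeric(length(comps))
  names(core_median) <- tmp_labels
  for (k in seq_along(comps)) {
    members <- comps[[k]]
    assign[members] <- tmp_labels[k]
    prov[members] <- "rbh"
    idx <- match(members, hits$id)
    sp <- hits$species[idx]
    sc <- hits$scores[idx, idx, drop = FALSE]
    cross <- outer(sp, sp, "!=") & upper.tri(sc)
    core_median[k] <- if (any(cross)) median(sc[cross]) else NA_real_
  }

  # in-paralog absorption for unplaced non-basal genes (valid first, then
  # remnant/pseudogene attachment by the same rule)
  for (pass_status in list("valid", c("pseudogene", "remnant"))) {
    unplaced <- records$id[is.na(assign[records$id]) &
                           records$status %in% pass_status &
                           records$species != basal]
    for (g in sort(unplaced)) {
      gi <- match(g, hits$id)
      other <- which(hits$species != hits$species[gi] & hits$id != g &
                     !is.na(assign[hits$id]))
      if (!length(other)) next
      sc <- hits$scores[gi, other]
      o <- order(-sc, hits$id[other])
      top <- other[o[1]]
      og <- assign[hits$id[top]]
      med <- core_median[og]
      if (!is.na(med) && hits$scores[gi, top] >= in_paralog_ratio * med) {
        assign[g] <- og
        prov[g] <- "in-paralog"
      }
    }
  }

  # outgroup attachment: reciprocity against >= 1 member
  basal_ids <- records$id[records$species == basal & records$status == "valid"]
  best <- best_hit_per_species(hits, hits$id %in% records$id[records$status == "valid"])
  for (g in sort(basal_ids)) {
    gi <- match(g, hits$id)
    cand <- which(hits$species != basal & !is.na(assign[hits$id]))
    if (!length(cand)) next
    sc <- hits$scores[gi, cand]
    o <- order(-sc, hits$id[cand])
    top <- hits$id[cand[o[1]]]
    og <- assign[top]
    members <- names(assign)[!is.na(assign) & assign == og]
    members <- setdiff(members, basal_ids)
    reciprocal <- any(vapply(members, function(m) {
      bm <- best[[m]]
      !is.null(bm) && !is.na(bm[basal]) && bm[basal] == g
    }, TRUE))
    if (reciprocal) {
      assign[g] <- og
      prov[g] <- "outgroup-attach"
    }
  }

  if (!is.null(manual_overrides)) {
    for (k in seq_len(nrow(manual_overrides))) {
      g <- manual_overrides$id[k]
      if (!g %in% names(assign)) stop("manual override for unknown gene: ", g)
      assign[g] <- manual_overrides$og_id[k]
      prov[g] <- "manual"
    }
  }

  # deterministic labels: sort groups by smallest member id
  groups <- split(names(assign)[!is.na(assign)], assign[!is.na(assign)])
  manual_named <- !grepl("^tmp[0-9]+$", names(groups))
  auto <- groups[!manual_named]
  if (length(auto)) {
    o <- order(vapply(auto, function(m) min(m), ""))
    auto <- auto[o]
    names(auto) <- sprintf("OG_%03d", seq_along(auto))
  }
  groups <- c(auto, groups[manual_named])
  final <- setNames(rep(NA_character_, length(assign)), names(assign))
  for (lab in names(groups)) final[groups[[lab]]] <- lab

  assigned <- !is.na(final)
  assignments <- data.frame(
    id = names(final)[assigned],
    species = records$species[match(names(final)[assigned], records$id)],
    og_id = unname(final[assigned]),
    provenance = unname(prov[assigned]),
    stringsAsFactors = FALSE)
  assignments <- assignments[order(assignments$og_id, assignments$id), ]
  rownames(assignments) <- NULL
  structure(list(og_ids = names(groups)[order(names(groups))],
                 assignments = assignments,
                 unassigned = sort(names(final)[!assigned]),
                 outgroup_specific = character(0)),
            class = "orthogroup_set")
}

#' @export
print.orthogroup_set <- function(x, ...) {
  cat("orthogroup_set:", length(x$og_ids), "orthogroups,",
      nrow(x$assignments), "assigned genes,",
      length(x$unassigned), "unassigned\n")
  invisible(x)
}

#' Write orthogroup assignments as TSV
#' @param ogs \code{orthogroup_set}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_og_assignments <- function(ogs, path) {
  write.table(ogs$assignments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Diagnostically classify a query protein against a curated reference
#'
#' Assigns the query to the orthogroup of its top-scoring reference hit when
#' the score margin over the best hit in any other orthogroup is at least
#' \code{min_margin} times the top score and reciprocity holds: scored against
#' the reference genes of the query's species plus the query, the query ranks
#' within the top \code{k} hits of that reference member once members of the
#' candidate orthogroup itself are set aside (in-paralogs of the candidate
#' group outranking the query corroborate membership rather than contradict
#' it).  The top score must additionally clear a composition-matched null:
#' the query is re-scored against the best member after \code{n_null}
#' within-sequence shuffles, and the observed score must lie \code{z_min}
#' null standard deviations above the null mean, so compositionally plausible
#' but unrelated sequences are not assigned.  Otherwise the query is reported
#' unassigned.
#'
#' @param query single-row \code{protein_records}.
#' @param reference \code{protein_records}; every record must carry an og_id.
#' @param scheme \code{\link{scoring_scheme}}.
#' @param min_margin margin threshold as a fraction of the top score.
#' @param k reciprocity window.
#' @param n_null shuffled-query null replicates for the score floor.
#' @param z_min required z-score of the observed top score against the null.
#' @return list of class \code{classification_result}: query id, assigned
#'   og_id (or \code{"unassigned"}), best score, margin and reciprocal_ok.
#' @export
classify_query <- function(query, reference, scheme = scoring_scheme(),
                           min_margin = 0.05, k = 3, n_null = 20, z_min = 3) {
  if (nrow(reference) == 0) stop("empty reference")
  if (anyNA(reference$og_id)) stop("every reference record needs an og_id")
  hits <- rank_hits(query, reference, scheme)
  hits <- hits[hits$target != query$id[[1]], , drop = FALSE]
  og <- reference$og_id[match(hits$target, reference$id)]
  best <- hits$score[1]
  best_og <- og[1]
  other <- hits$score[og != best_og]
  margin <- if (length(other)) best - max(other) else best
  # reciprocity: query within the member's top-k hits among the query's
  # species (reference genes of that species plus the query itself)
  member <- reference[reference$id == hits$target[1], , drop = FALSE]
  pool <- rbind(reference[reference$species == query$species[[1]] &
                          !reference$id %in% c(member$id, query$id[[1]]), ,
                          drop = FALSE], query)
  back <- rank_hits(member, pool, scheme)
  back_og <- reference$og_id[match(back$target, reference$id)]
  back <- back[back$target == query$id[[1]] | is.na(back_og) | back_og != best_og,
               , drop = FALSE]
  reciprocal_ok <- query$id[[1]] %in% back$target[seq_len(min(k, nrow(back)))]
  # composition-matched score floor (deterministic: RNG state is restored)
  score_ok <- TRUE
  if (n_null >= 2 && best > 0) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    }
    set.seed(nchar(query$sequence[[1]]) + nrow(reference))
    qchars <- strsplit(query$sequence[[1]], "")[[1]]
    # each shuffle is scored against the whole reference and the maximum is
    # taken, mirroring the selection of the observed top hit
    null_scores <- vapply(seq_len(n_null), function(b) {
      shuf <- paste(sample(qchars), collapse = "")
      max(.cpp_local_scores(shuf, reference$sequence, scheme$matrix,
                            scheme$letters, scheme$gap_open, scheme$gap_extend))
    }, 0)
    z <- (best - mean(null_scores)) / max(stats::sd(null_scores), 1e-9)
    score_ok <- z >= z_min
  }
  assigned <- best > 0 && margin >= min_margin * best && reciprocal_ok && score_ok
  structure(list(query = query$id[[1]],
                 og_id = if (assigned) best_og else "unassigned",
                 best_score = best, margin = margin,
                 reciprocal_ok = reciprocal_ok),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("query %s -> %s (score %.1f, margin %.1f, reciprocal %s)\n",
              x$query, x$og_id, x$best_score, x$margin, x$reciprocal_ok))
  invisible(x)
}
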