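#' Build the OG-by-species count matrix from inferred orthogroups
#'
#' Counts valid-status members per (OG, species) cell; attached
#' remnant/pseudogene records set the cell's remnant flag without contributing
#' to the count.  Orthogroups flagged outgroup-specific are kept as separate
#' rows excluded from OG counting.
#'
#' @param ogs an \code{orthogroup_set} (see \code{\link{build_orthogroups}}).
#' @param records the \code{protein_records} the orthogroups were built from.
#' @param registry \code{species_registry} fixing the column order.
#' @return \code{count_matrix}.
#' @export
build_matrix <- function(ogs, records, registry) {
  stopifnot(inherits(ogs, "orthogroup_set"))
  assign <- ogs$assignments
  unknown <- setdiff(unique(assign$species), registry$code)
  if (length(unknown)) stop("OG member species not in registry: ",
                            paste(unknown, collapse = ", "))
  og_ids <- ogs$og_ids
  counts <- matrix(0L, length(og_ids), nrow(registry),
                   dimnames = list(og_ids, registry$code))
  flags <- matrix(FALSE, length(og_ids), nrow(registry),
                  dimnames = list(og_ids, registry$code))
  status <- records$status[match(assign$id, records$id)]
  valid <- assign[status == "valid", , drop = FALSE]
  if (nrow(valid)) {
    tab <- table(factor(valid$og_id, levels = og_ids),
                 factor(valid$species, levels = registry$code))
    counts[] <- as.integer(tab)
  }
  remn <- assign[status %in% c("remnant", "pseudogene"), , drop = FALSE]
  if (nrow(remn))
    flags[cbind(match(remn$og_id, og_ids), match(remn$species, registry$code))] <- TRUE
  count_matrix(counts, flags, ogs$outgroup_specific)
}

#' Summary statistics of a count matrix
#'
#' Reports per-species and per-OG totals, the grand total, the mean number of
#' genes per species (and its nearest-integer rounding), the largest OG, the
#' number of OG rows (outgroup-specific rows excluded) and the number of
#' distinct subfamilies obtained by stripping the trailing hyphen-numeral
#' suffix from OG labels.  Species totals include genes in outgroup-specific
#' rows; the OG-row and subfamily counts exclude those rows.
#'
#' @param object \code{count_matrix}.
#' @param ... unused.
#' @return list of class \code{count_matrix_summary}.
#' @export
summary.count_matrix <- function(object, ...) {
  cm <- object
  og_rows <- setdiff(rownames(cm$counts), cm$outgroup_specific_rows)
  species_totals <- colSums(cm$counts)
  og_totals <- rowSums(cm$counts)[og_rows]
  grand <- sum(cm$counts)
  mean_per_species <- grand / ncol(cm$counts)
  subfam <- og_subfamily_label(og_rows)
  multi <- sum(table(subfam) >= 2)
  largest <- if (length(og_totals)) names(og_totals)[which.max(og_totals)] else NA_character_
  out <- list(species_totals = species_totals,
              og_totals = og_totals,
              grand_total = grand,
              mean_per_species = mean_per_species,
              mean_per_species_rounded = as.integer(round(mean_per_species)),
              largest_og = largest,
              largest_og_size = if (is.na(largest)) NA_integer_ else unname(og_totals[largest]),
              n_og_rows = length(og_rows),
              n_subfamilies = length(unique(subfam)),
              n_multi_og_subfamilies = multi)
  class(out) <- "count_matrix_summary"
  out
}

#' @export
print.count_matrix_summary <- function(x, ...) {
  cat("Gene family matrix summary\n")
  cat("  genes:", x$grand_total, " OG rows:", x$n_og_rows,
      " subfamilies:", x$n_subfamilies,
      "(", x$n_multi_og_subfamilies, "with >1 OG )\n")
  cat("  mean genes/species:", round(x$mean_per_species, 2),
      "(~", x$mean_per_species_rounded, ")\n")
  cat("  largest OG:", x$largest_og, "with", x$largest_og_size, "genes\n")
  cat("  per-species totals:\n")
  print(x$species_totals)
  invisible(x)
}

#' Number of orthogroups with no member in a species
#'
#' Counts OG rows (outgroup-specific rows excluded) whose cell for the species
#' is zero with no remnant flag — i.e. lineages where the gene is truly
#' missing rather than degraded.  When a registry is supplied, OGs missing
#' across the species' entire lineage class (all sampled monocots or all
#' sampled dicots) are excluded: such absences are attributed to the wider
#' clade, not to the species, matching how per-species missing counts are
#' reported in the gene-family literature.
#'
#' @param cm \code{count_matrix}.
#' @param species species code.
#' @param registry optional \code{species_registry} enabling the lineage-wide
#'   exclusion.
#' @return integer.
#' @export
missing_og_count <- function(cm, species, registry = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!species %in% colnames(cm$counts)) stop("unknown species: ", species)
  og_rows <- setdiff(rownames(cm$counts), cm$outgroup_specific_rows)
  zero <- cm$counts[og_rows, , drop = FALSE] == 0 &
    !cm$remnant_flags[og_rows, , drop = FALSE]
  miss <- zero[, species]
  if (!is.null(registry)) {
    lin <- registry$lineage[match(species, registry$code)]
    mates <- intersect(registry$code[registry$lineage == lin], colnames(cm$counts))
    if (length(mates) >= 2) {
      lineage_wide <- rowSums(zero[, mates, drop = FALSE]) == length(mates)
      miss <- miss & !lineage_wide
    }
  }
  sum(miss)
}

#' Call lineage-level gene losses
#'
#' For each OG and each maximal clade whose sampled species all lack the gene
#' (count 0, no remnant), emits a loss call at that clade with evidence level
#' \code{sampled-only}.  An optional evidence table of
#' (og_id, clade, status in present/absent) — standing in for database searches
#' across wider taxon sets — lifts a call to a wider clade when the OG is
#' absent there, or restricts it to a narrower clade when a sister lineage
#' inside the called clade is known to retain the gene.
#'
#' @param cm \code{count_matrix}.
#' @param tax \code{taxonomy} (its species must cover the matrix columns).
#' @param evidence optional data.frame with columns og_id, clade, status.
#' @return data.frame with columns og_id, clade, evidence_level, note.
#' @export
call_losses <- function(cm, tax, evidence = NULL) {
  stopifnot(inherits(cm, "count_matrix"), inherits(tax, "taxonomy"))
  species <- colnames(cm$counts)
  if (!all(species %in% tax$tree$tip.label))
    stop("taxonomy does not cover matrix species")
  if (!is.null(evidence)) {
    bad <- setdiff(unique(evidence$clade), names(tax$clades))
    if (length(bad)) stop("evidence clade(s) not in taxonomy: ",
                          paste(bad, collapse = ", "))
  }
  og_rows <- setdiff(rownames(cm$counts), cm$outgroup_specific_rows)
  clade_names <- names(tax$clades)
  calls <- list()
  for (og in og_rows) {
    zero <- species[cm$counts[og, ] == 0 & !cm$remnant_flags[og, ]]
    if (!length(zero)) next
    ok <- vapply(clade_names, function(cl) {
      s <- intersect(tax$clades[[cl]], species)
      length(s) > 0 && all(s %in% zero)
    }, TRUE)
    cand <- clade_names[ok]
    # maximal: drop clades whose sampled set is strictly inside another's, or
    # equal with a lower specificity level
    keep <- vapply(cand, function(a) {
      sa <- intersect(tax$clades[[a]], species)
      !any(vapply(setdiff(cand, a), function(b) {
        sb <- intersect(tax$clades[[b]], species)
        all(sa %in% sb) && (length(sb) > length(sa) ||
          (length(sb) == length(sa) && tax$levels[b] > tax$levels[a]))
      }, TRUE))
    }, TRUE)
    for (cl in cand[keep]) {
      call <- list(og_id = og, clade = cl, evidence_level = "sampled-only", note = "")
      if (!is.null(evidence)) {
        ev <- evidence[evidence$og_id == og, , drop = FALSE]
        sampled <- intersect(tax$clades[[cl]], species)
        # widen: absent across a clade containing this one
        abs_rows <- ev[ev$status == "absent", , drop = FALSE]
        widest <- call$clade
        for (wc in abs_rows$clade) {
          sw <- intersect(tax$clades[[wc]], species)
          cur <- intersect(tax$clades[[widest]], species)
          if (all(cur %in% sw) &&
              (length(sw) > length(cur) || tax$levels[wc] >= tax$levels[widest])) {
            widest <- wc
            call$evidence_level <- "wider-taxon"
            call$note <- paste0("absent across ", wc, " by external evidence")
          }
        }
        call$clade <- widest
        # restrict: presence in a sister lineage inside the called clade
        pres_rows <- ev[ev$status == "present", , drop = FALSE]
        for (pc in pres_rows$clade) {
          sp <- intersect(tax$clades[[pc]], species)
          cur <- intersect(tax$clades[[call$clade]], species)
          if (all(cur %in% sp)) {
            # narrowest candidate clade still covering the sampled zeros,
            # strictly below the present clade
            narrower <- Filter(function(nc) {
              sn <- intersect(tax$clades[[nc]], species)
              setequal(sn, cur) && tax$levels[nc] < tax$levels[pc] &&
                nc != pc
            }, cand)
            if (length(narrower)) {
              lv <- tax$levels[unlist(narrower)]
              call$clade <- narrower[[which.max(lv)]]
              call$evidence_level <- "wider-taxon"
              call$note <- paste0("present in other ", pc,
                                  "; loss restricted to ", call$clade)
            }
          }
        }
      }
      calls[[length(calls) + 1]] <- call
    }
  }
  if (!length(calls))
    return(data.frame(og_id = character(0), clade = character(0),
                      evidence_level = character(0), note = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(calls, as.data.frame, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
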