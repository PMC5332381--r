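#' Construct an OG-by-species count matrix
#'
#' Holds non-negative gene counts per (orthogroup, species) cell together with
#' per-cell remnant flags (a remnant is a degraded copy detectable in the
#' genome but not annotated as a functional gene model) and the set of
#' outgroup-specific rows that are kept in the table but excluded from
#' orthogroup counting.
#'
#' @param counts integer matrix, rows = OGs, columns = species codes.
#' @param remnant_flags logical matrix of the same shape (default all FALSE).
#' @param outgroup_specific_rows character vector of row labels excluded from
#'   the OG-row count (their genes still count in species totals).
#' @return list of class \code{count_matrix}.
#' @export
count_matrix <- function(counts, remnant_flags = NULL, outgroup_specific_rows = character(0)) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have OG row names and species column names")
  if (anyDuplicated(rownames(counts))) stop("duplicate OG row labels")
  if (anyDuplicated(colnames(counts))) stop("duplicate species column labels")
  if (is.null(remnant_flags)) {
    remnant_flags <- matrix(FALSE, nrow(counts), ncol(counts),
                            dimnames = dimnames(counts))
  }
  remnant_flags <- as.matrix(remnant_flags)
  if (!identical(dim(remnant_flags), dim(counts)))
    stop("remnant_flags shape must match counts")
  dimnames(remnant_flags) <- dimnames(counts)
  missing_rows <- setdiff(outgroup_specific_rows, rownames(counts))
  if (length(missing_rows))
    stop("outgroup-specific rows not in matrix: ", paste(missing_rows, collapse = ", "))
  structure(list(counts = counts, remnant_flags = remnant_flags,
                 outgroup_specific_rows = outgroup_specific_rows),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "rows x", ncol(x$counts), "species;",
      sum(x$counts), "genes\n")
  if (length(x$outgroup_specific_rows))
    cat(" outgroup-specific rows:", paste(x$outgroup_specific_rows, collapse = ", "), "\n")
  invisible(x)
}

#' Read a printed count-matrix TSV
#'
#' Cell grammar of the printed table dialect: a bare integer; an integer
#' followed by \code{*} (remnant also present); a bare \code{*} (remnant only,
#' stored as count 0 with the remnant flag set); or \code{-} / U+2212 for
#' missing (count 0, no flag).  Lines of the form
#' \code{# outgroup_specific: LABEL[, LABEL...]} declare outgroup-specific rows.
#'
#' @param path TSV file; first column OG labels, remaining columns species.
#' @return \code{count_matrix}.
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) stop("count matrix file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  og_specific <- character(0)
  meta <- grep("^#", lines)
  for (m in meta) {
    mm <- regmatches(lines[m], regexec("^#\\s*outgroup_specific:\\s*(.+)$", lines[m]))[[1]]
    if (length(mm) == 2)
      og_specific <- c(og_specific, trimws(strsplit(mm[2], ",")[[1]]))
  }
  lines <- lines[setdiff(seq_along(lines), meta)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("count matrix must have a header and at least one row")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  species <- header[-1]
  ncols <- length(header)
  rows <- cells[-1]
  ragged <- vapply(rows, length, 0L) != ncols
  if (any(ragged))
    stop("ragged row(s) at line(s): ", paste(which(ragged) + 1, collapse = ", "))
  og_ids <- vapply(rows, `[[`, "", 1L)
  counts <- matrix(0L, length(rows), length(species),
                   dimnames = list(og_ids, species))
  flags <- matrix(FALSE, length(rows), length(species),
                  dimnames = list(og_ids, species))
  for (i in seq_along(rows)) {
    for (j in seq_along(species)) {
      tok <- trimws(rows[[i]][j + 1])
      parsed <- parse_count_cell(tok)
      if (is.null(parsed))
        stop(sprintf("non-conforming cell '%s' at row %s, column %s",
                     tok, og_ids[i], species[j]))
      counts[i, j] <- parsed$count
      flags[i, j] <- parsed$remnant
    }
  }
  count_matrix(counts, flags, og_specific)
}

# one printed cell -> list(count, remnant) or NULL if malformed
parse_count_cell <- function(tok) {
  if (tok %in% c("-", "−")) return(list(count = 0L, remnant = FALSE))
  if (tok == "*") return(list(count = 0L, remnant = TRUE))
  if (grepl("^[0-9]+\\*$", tok))
    return(list(count = as.integer(sub("\\*$", "", tok)), remnant = TRUE))
  if (grepl("^[0-9]+$", tok)) return(list(count = as.integer(tok), remnant = FALSE))
  NULL
}

#' Write a count matrix in the printed-table dialect
#' @param x \code{count_matrix}.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  tok <- matrix("", nrow(x$counts), ncol(x$counts))
  tok[] <- as.character(x$counts)
  tok[x$counts == 0 & !x$remnant_flags] <- "-"
  tok[x$counts == 0 & x$remnant_flags] <- "*"
  sel <- x$counts > 0 & x$remnant_flags
  tok[sel] <- paste0(x$counts[sel], "*")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(x$outgroup_specific_rows))
    writeLines(paste0("# outgroup_specific: ",
                      paste(x$outgroup_specific_rows, collapse = ", ")), con)
  writeLines(paste(c("og_id", colnames(x$counts)), collapse = "\t"), con)
  for (i in seq_len(nrow(x$counts)))
    writeLines(paste(c(rownames(x$counts)[i], tok[i, ]), collapse = "\t"), con)
  invisible(path)
}
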