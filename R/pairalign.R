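#' Scoring scheme for pairwise protein alignment
#'
#' Bundles a symmetric substitution matrix with affine gap penalties.  A gap of
#' length L costs \code{gap_open + (L - 1) * gap_extend} (EMBOSS accounting).
#' The default is BLOSUM62 with open 10 / extend 0.5, with X rescored to 0
#' against everything so unknown residues are neutral.
#'
#' @param matrix substitution matrix name (\code{"BLOSUM62"}, \code{"BLOSUM50"},
#'   \code{"PAM250"}, ...; any matrix shipped with Biostrings) or a numeric
#'   matrix with residue dimnames.
#' @param gap_open,gap_extend non-negative penalties, \code{gap_extend <= gap_open}.
#' @return list of class \code{scoring_scheme}.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 10, gap_extend = 0.5) {
  if (is.character(matrix)) {
    env <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = env)
    mat <- get(matrix, envir = env)
  } else {
    mat <- as.matrix(matrix)
  }
  if (is.null(rownames(mat)) || !identical(rownames(mat), colnames(mat)))
    stop("substitution matrix must be square with identical residue dimnames")
  if (max(abs(mat - t(mat))) > 0) stop("substitution matrix must be symmetric")
  if (gap_open < 0 || gap_extend < 0 || gap_extend > gap_open)
    stop("need 0 <= gap_extend <= gap_open")
  if ("X" %in% rownames(mat)) {
    mat["X", ] <- 0
    mat[, "X"] <- 0
  }
  structure(list(matrix = mat, letters = rownames(mat),
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' Read a substitution matrix in NCBI text format
#'
#' @param path matrix file (comment lines start with \code{#}; first
#'   non-comment line lists the column residues).
#' @return numeric matrix with residue dimnames, usable in
#'   \code{\link{scoring_scheme}}.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- strsplit(trimws(lines[-1]), "\\s+")
  rows <- vapply(body, `[[`, "", 1L)
  vals <- t(vapply(body, function(x) as.numeric(x[-1]), numeric(length(cols))))
  dimnames(vals) <- list(rows, cols)
  vals
}

finish_alignment <- function(res, mode, scheme) {
  a <- res$aligned_a; b <- res$aligned_b
  len <- nchar(a)
  if (len > 0) {
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    aligned <- ca != "-" & cb != "-"
    ident <- sum(aligned & ca == cb)
    pos <- 0L
    if (any(aligned))
      pos <- sum(scheme$matrix[cbind(ca[aligned], cb[aligned])] > 0)
    identity_pct <- 100 * ident / len
    similarity_pct <- 100 * pos / len
  } else {
    identity_pct <- similarity_pct <- 0
  }
  structure(list(aligned_a = a, aligned_b = b, score = res$score, mode = mode,
                 identity_pct = identity_pct, similarity_pct = similarity_pct,
                 alignment_length = len),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("%s alignment: score %.1f, length %d, identity %.1f%%, similarity %.1f%%\n",
              x$mode, x$score, x$alignment_length, x$identity_pct, x$similarity_pct))
  if (x$alignment_length > 0 && x$alignment_length <= 120) {
    cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  }
  invisible(x)
}

#' Optimal global (Needleman-Wunsch) alignment with affine gaps
#'
#' Identity is identical columns over the full alignment length (gap columns
#' included); similarity counts columns whose substitution score is positive
#' (identities included) over the same denominator — the EMBOSS convention.
#' Traceback ties are resolved in the fixed order
#' match/mismatch > gap-in-a > gap-in-b, so results are deterministic.
#'
#' @param a,b non-empty amino-acid strings.
#' @param scheme \code{\link{scoring_scheme}}.
#' @return \code{alignment_result} with aligned strings, score, identity and
#'   similarity percentages and alignment length.
#' @export
align_global <- function(a, b, scheme = scoring_scheme()) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  res <- .cpp_align_global(toupper(a), toupper(b), scheme$matrix, scheme$letters,
                           scheme$gap_open, scheme$gap_extend)
  finish_alignment(res, "global", scheme)
}

#' Optimal local (Smith-Waterman) alignment with affine gaps
#'
#' The score is never negative; sequences sharing no positively-scoring
#' residue pair yield score 0 and an empty alignment.
#'
#' @inheritParams align_global
#' @return \code{alignment_result}.
#' @export
align_local <- function(a, b, scheme = scoring_scheme()) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  res <- .cpp_align_local(toupper(a), toupper(b), scheme$matrix, scheme$letters,
                          scheme$gap_open, scheme$gap_extend)
  finish_alignment(res, "local", scheme)
}

#' Rank database hits for a query protein
#'
#' Scores the query against every database record by optimal local alignment
#' and returns hits sorted by descending score, ties broken by ascending
#' target id.  A self-hit is included when the query is in the database.
#'
#' @param query single-row \code{protein_records} (or a list with id, species,
#'   sequence).
#' @param database \code{protein_records}.
#' @param scheme \code{\link{scoring_scheme}}.
#' @return data.frame (target, species, score), best hit first.
#' @export
rank_hits <- function(query, database, scheme = scoring_scheme()) {
  if (nrow(database) == 0) stop("database must be non-empty")
  scores <- .cpp_local_scores(query$sequence[[1]], database$sequence,
                              scheme$matrix, scheme$letters,
                              scheme$gap_open, scheme$gap_extend)
  ord <- order(-scores, database$id)
  data.frame(target = database$id[ord], species = database$species[ord],
             score = scores[ord], stringsAsFactors = FALSE)
}

#' All-vs-all hit table
#'
#' Computes local alignment scores for every pair of records (one symmetric
#' pass) and returns the per-query ranked hit lists used by orthogroup
#' inference.
#'
#' @param records \code{protein_records}.
#' @param scheme \code{\link{scoring_scheme}}.
#' @return object of class \code{hit_table}: list with the score matrix and
#'   the records' id/species vectors.
#' @export
hit_table <- function(records, scheme = scoring_scheme()) {
  stopifnot(nrow(records) >= 2)
  scores <- .cpp_local_score_matrix(records$sequence, scheme$matrix,
                                    scheme$letters, scheme$gap_open,
                                    scheme$gap_extend)
  dimnames(scores) <- list(records$id, records$id)
  structure(list(scores = scores, id = records$id, species = records$species),
            class = "hit_table")
}

#' @export
print.hit_table <- function(x, ...) {
  cat("hit_table:", length(x$id), "records,",
      length(unique(x$species)), "species\n")
  invisible(x)
}

#' Import externally computed hits in BLAST tabular format
#'
#' Reads 12-column tabular output (qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore); qseqid, sseqid and
#' bitscore are used.  For reciprocal pairs reported twice the maximum
#' bitscore is kept, so imported tables satisfy the same symmetric-score
#' contract as internally computed ones.
#'
#' @param path tabular hits file.
#' @param records \code{protein_records} covering every id in the file.
#' @return \code{hit_table}.
#' @export
read_blast_tab <- function(path, records) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 12) stop("expected 12-column BLAST tabular format")
  q <- tab[[1]]; s <- tab[[2]]; bits <- as.numeric(tab[[12]])
  unknown <- setdiff(unique(c(q, s)), records$id)
  if (length(unknown)) stop("hit ids not in records: ",
                            paste(head(unknown, 5), collapse = ", "))
  n <- nrow(records)
  scores <- matrix(0, n, n, dimnames = list(records$id, records$id))
  iq <- match(q, records$id); is <- match(s, records$id)
  for (k in seq_along(iq)) {
    v <- max(scores[iq[k], is[k]], bits[k])
    scores[iq[k], is[k]] <- v
    scores[is[k], iq[k]] <- v
  }
  structure(list(scores = scores, id = records$id, species = records$species),
            class = "hit_table")
}
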