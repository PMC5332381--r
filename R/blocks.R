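#' Multiple sequence alignment container
#'
#' @param ids sequence identifiers.
#' @param rows equal-length gapped sequences (gap character \code{-}).
#' @return list of class \code{msa}.
#' @export
msa <- function(ids, rows) {
  stopifnot(length(ids) == length(rows), length(ids) >= 1)
  if (anyDuplicated(ids)) stop("duplicate ids in MSA")
  w <- unique(nchar(rows))
  if (length(w) != 1) stop("all MSA rows must have the same length")
  structure(list(ids = as.character(ids), rows = toupper(as.character(rows)),
                 width = w), class = "msa")
}

#' Read an aligned FASTA file as an MSA
#' @param path aligned FASTA.
#' @return \code{msa}; ids are the full headers (no species parsing).
#' @export
read_msa <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  msa(sub("\\s.*$", "", names(aa)), as.character(aa))
}

#' Write an MSA as aligned FASTA
#' @param x \code{msa}.
#' @param path output file.
#' @export
write_msa <- function(x, path) {
  seqs <- Biostrings::AAStringSet(x$rows)
  names(seqs) <- x$ids
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' @export
print.msa <- function(x, ...) {
  cat("msa:", length(x$ids), "sequences x", x$width, "columns\n")
  invisible(x)
}

msa_chars <- function(x) {
  do.call(rbind, strsplit(x$rows, ""))
}

#' Select conserved alignment blocks
#'
#' Relaxed Gblocks-style column selection.  A column is conserved when its
#' modal residue frequency (gaps counting against it) reaches
#' \code{min_conserved_frac} and its gap content is admissible under
#' \code{gap_policy} (\code{"none"}: no gaps; \code{"half"}: at most 50\%
#' gaps; \code{"all"}: any).  Candidate blocks are split wherever more than
#' \code{max_nonconserved_run} consecutive non-conserved columns occur, then
#' trimmed at both flanks back to columns whose modal frequency reaches
#' \code{min_flank_frac}; blocks shorter than \code{min_block_length} are
#' discarded.  The relaxed defaults mirror small final blocks, gaps allowed
#' within blocks, and less strict flanks.
#'
#' @param x \code{msa}.
#' @param min_conserved_frac modal-residue frequency for a conserved column.
#' @param min_flank_frac frequency required of block end columns
#'   (default: same as \code{min_conserved_frac}).
#' @param max_nonconserved_run longest tolerated run of non-conserved columns
#'   inside a block.
#' @param min_block_length minimum kept block length (>= 1).
#' @param gap_policy \code{"none"}, \code{"half"} or \code{"all"}.
#' @return list of class \code{block_selection}: kept_columns (1-based),
#'   blocks (start, end), and the parameters used.
#' @export
select_blocks <- function(x, min_conserved_frac = 0.5,
                          min_flank_frac = min_conserved_frac,
                          max_nonconserved_run = 8, min_block_length = 5,
                          gap_policy = c("half", "none", "all")) {
  stopifnot(inherits(x, "msa"))
  gap_policy <- match.arg(gap_policy)
  if (min_block_length < 1) stop("min_block_length must be >= 1")
  ch <- msa_chars(x)
  n <- nrow(ch)
  # modal frequency among non-gap residues; gap content is judged separately
  modal_freq <- apply(ch, 2, function(col) {
    res <- col[col != "-"]
    if (!length(res)) return(0)
    max(table(res)) / length(res)
  })
  gap_frac <- colMeans(ch == "-")
  gap_ok <- switch(gap_policy,
                   none = gap_frac == 0,
                   half = gap_frac <= 0.5,
                   all  = rep(TRUE, ncol(ch)))
  conserved <- modal_freq >= min_conserved_frac & gap_ok
  flank_ok <- modal_freq >= min_flank_frac & gap_ok

  # split at runs of > max_nonconserved_run non-conserved columns
  blocks <- list()
  ncols <- ncol(ch)
  run <- 0L
  seg_start <- NA_integer_
  close_segment <- function(s, e) {
    # trim flanks to flank-admissible columns
    while (s <= e && !flank_ok[s]) s <- s + 1L
    while (e >= s && !flank_ok[e]) e <- e - 1L
    if (s <= e && (e - s + 1L) >= min_block_length) list(c(s, e)) else list()
  }
  i <- 1L
  while (i <= ncols) {
    if (conserved[i]) {
      if (is.na(seg_start)) seg_start <- i
      run <- 0L
    } else if (!is.na(seg_start)) {
      run <- run + 1L
      if (run > max_nonconserved_run) {
        blocks <- c(blocks, close_segment(seg_start, i - run))
        seg_start <- NA_integer_
        run <- 0L
      }
    }
    i <- i + 1L
  }
  if (!is.na(seg_start)) blocks <- c(blocks, close_segment(seg_start, ncols - run))
  kept <- unlist(lapply(blocks, function(b) seq(b[1], b[2])))
  if (is.null(kept)) kept <- integer(0)
  structure(list(kept_columns = kept,
                 blocks = if (length(blocks))
                   data.frame(start = vapply(blocks, `[`, 0L, 1),
                              end = vapply(blocks, `[`, 0L, 2))
                 else data.frame(start = integer(0), end = integer(0)),
                 parameters = list(min_conserved_frac = min_conserved_frac,
                                   min_flank_frac = min_flank_frac,
                                   max_nonconserved_run = max_nonconserved_run,
                                   min_block_length = min_block_length,
                                   gap_policy = gap_policy)),
            class = "block_selection")
}

#' @export
print.block_selection <- function(x, ...) {
  cat("block_selection:", length(x$kept_columns), "kept columns in",
      nrow(x$blocks), "block(s)\n")
  invisible(x)
}

#' Write kept column ranges as TSV (1-based inclusive)
#' @param sel \code{block_selection}.
#' @param path output file.
#' @export
write_block_selection <- function(sel, path) {
  write.table(sel$blocks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pairwise distances over selected alignment blocks
#'
#' p-distance over the kept, mutually ungapped columns of each pair, with an
#' optional Poisson correction \eqn{d = -\ln(1 - p)}.
#'
#' @param x \code{msa} with at least two rows.
#' @param selection \code{block_selection}; kept columns must be non-empty.
#'   Columns may repeat (bootstrap resampling passes resampled column sets).
#' @param correction \code{"p"} or \code{"poisson"}.
#' @return symmetric distance matrix with zero diagonal, labelled by ids.
#' @export
block_distance <- function(x, selection, correction = c("poisson", "p")) {
  correction <- match.arg(correction)
  stopifnot(inherits(x, "msa"))
  if (length(x$ids) < 2) stop("need at least 2 sequences")
  cols <- if (inherits(selection, "block_selection")) selection$kept_columns else selection
  if (!length(cols)) stop("no kept columns")
  ch <- msa_chars(x)[, cols, drop = FALSE]
  n <- length(x$ids)
  d <- matrix(0, n, n, dimnames = list(x$ids, x$ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- ch[i, ] != "-" & ch[j, ] != "-"
      if (!any(ok))
        stop("no comparable columns between ", x$ids[i], " and ", x$ids[j])
      p <- mean(ch[i, ok] != ch[j, ok])
      if (correction == "poisson") {
        if (p >= 1) stop("saturated pair (p = 1) cannot be Poisson-corrected: ",
                         x$ids[i], " vs ", x$ids[j])
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}
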