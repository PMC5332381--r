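#' Extract the variable N-terminal region of a protein
#'
#' Returns the residues strictly before the conserved C-terminal domain.  The
#' domain start is taken from the record's \code{domain_start} when set;
#' otherwise it is estimated from an anchor alignment as the per-sequence
#' residue position of the first conserved-block column.
#'
#' @param record single-row \code{protein_records}.
#' @param anchor optional list with elements \code{msa} (containing the
#'   record's id) and \code{selection} (\code{block_selection} on that MSA).
#' @return the N-terminal sequence (possibly empty, with a warning).
#' @export
extract_nterm <- function(record, anchor = NULL) {
  start <- record$domain_start[[1]]
  if (is.na(start)) {
    if (is.null(anchor)) stop("record has no domain_start and no anchor alignment given")
    start <- anchor_domain_start(anchor$msa, anchor$selection, record$id[[1]])
  }
  if (start <= 1) {
    warning("empty N-terminal region for ", record$id[[1]])
    return("")
  }
  substr(record$sequence[[1]], 1, start - 1)
}

#' Estimate per-sequence domain starts from an anchor alignment
#'
#' Locates the boundary between the hypervariable N-terminal region and the
#' conserved domain as the least-squares change point of the per-column
#' conservation profile (modal residue frequency), then anchors it to the
#' first conserved-block column at or after that point.  The anchor column is
#' mapped to a residue position in each sequence as the number of non-gap
#' characters up to and including it.
#'
#' @param x \code{msa}.
#' @param selection \code{block_selection} on \code{x}.
#' @param id sequence id (or vector of ids).
#' @return integer vector of 1-based domain starts.
#' @export
anchor_domain_start <- function(x, selection, id = x$ids) {
  if (!length(selection$kept_columns)) stop("anchor selection has no kept columns")
  ch <- msa_chars(x)
  f <- apply(ch, 2, function(col) {
    res <- col[col != "-"]
    if (!length(res)) 0 else max(table(res)) / length(res)
  })
  b <- conservation_changepoint(f)
  after <- selection$kept_columns[selection$kept_columns >= b]
  first <- if (length(after)) min(after) else min(selection$kept_columns)
  idx <- match(id, x$ids)
  if (anyNA(idx)) stop("id(s) not in anchor MSA: ",
                       paste(id[is.na(idx)], collapse = ", "))
  vapply(idx, function(i) {
    prefix <- substr(x$rows[i], 1, first)
    max(1L, nchar(gsub("-", "", prefix)))
  }, 0L)
}

# least-squares two-segment change point of a numeric profile
conservation_changepoint <- function(f) {
  L <- length(f)
  if (L < 3) return(1L)
  cs <- cumsum(f); cs2 <- cumsum(f^2)
  best <- Inf; bb <- 1L
  for (b in 2:(L - 1)) {
    nl <- b - 1; nr <- L - b + 1
    sl <- cs[b - 1]; sr <- cs[L] - cs[b - 1]
    ss <- (cs2[b - 1] - sl^2 / nl) + (cs2[L] - cs2[b - 1] - sr^2 / nr)
    if (ss < best) { best <- ss; bb <- b }
  }
  bb
}

# encode sequences as integer vectors over the 20-letter alphabet; X -> NA
encode_aa <- function(seqs) {
  lapply(strsplit(toupper(seqs), ""), function(ch) {
    v <- match(ch, AA_ALPHABET)
    v
  })
}

zoops_background <- function(enc, pseudo = 0.01) {
  counts <- tabulate(unlist(enc)[!is.na(unlist(enc))], nbins = 20) + pseudo
  counts / sum(counts)
}

# one EM run at fixed width from a seed PWM; returns model and objective
zoops_em <- function(enc, w, pwm0, bg, gamma0 = 0.8, pseudo = 0.01,
                     max_iter = 100, tol = 1e-6) {
  n <- length(enc)
  lens <- vapply(enc, length, 0L)
  nwin <- lens - w + 1L
  usable <- which(nwin >= 1L)
  log_bg <- log(bg)
  pwm <- pwm0
  gamma <- gamma0
  ll_old <- -Inf
  ll_trace <- numeric(0)
  post <- vector("list", n)
  for (iter in seq_len(max_iter)) {
    log_odds <- log(pwm) - matrix(log_bg, 20, w)
    ll <- 0
    Z <- vector("list", n)
    for (i in usable) {
      s <- enc[[i]]
      m <- nwin[i]
      lr <- numeric(m)
      for (k in seq_len(w)) {
        res <- s[(k):(k + m - 1)]
        contrib <- log_odds[res, k]
        contrib[is.na(res)] <- 0       # X is background-neutral
        lr <- lr + contrib
      }
      # ZOOPS mixture: P(no site) = 1 - gamma; sites uniform over positions
      mix <- c(log(1 - gamma), log(gamma / m) + lr)
      mx <- max(mix)
      lse <- mx + log(sum(exp(mix - mx)))
      ll <- ll + lse
      zi <- exp(mix - lse)
      Z[[i]] <- zi[-1]                 # per-position site posterior
    }
    # MAP objective: likelihood plus the Dirichlet(1 + pseudo) log-prior that
    # the pseudocount M-step maximizes; monotone under EM
    ll_pen <- ll + pseudo * sum(log(pwm))
    ll_trace <- c(ll_trace, ll_pen)
    if (ll_pen < ll_old - 1e-6 * max(1, abs(ll_old)))
      stop("ZOOPS EM objective decreased — internal error")
    # M-step
    counts <- matrix(pseudo, 20, w)
    site_mass <- 0
    for (i in usable) {
      zi <- Z[[i]]
      site_mass <- site_mass + sum(zi)
      s <- enc[[i]]
      m <- nwin[i]
      for (k in seq_len(w)) {
        res <- s[(k):(k + m - 1)]
        keep <- !is.na(res)
        if (any(keep))
          counts[, k] <- counts[, k] + tabulate_weighted(res[keep], zi[keep])
      }
    }
    pwm <- sweep(counts, 2, colSums(counts), "/")
    gamma <- min(max(site_mass / length(usable), 1e-6), 1 - 1e-6)
    post <- Z
    if (is.finite(ll_old) && abs(ll_pen - ll_old) < tol) break
    ll_old <- ll_pen
  }
  # expected log-likelihood-ratio objective of the fitted sites
  llr <- 0
  sites <- data.frame(id = integer(0), start = integer(0), score = numeric(0))
  log_odds <- log(pwm) - matrix(log(bg), 20, w)
  site_list <- vector("list", n)
  for (i in usable) {
    zi <- post[[i]]
    p_site <- sum(zi)
    if (p_site >= 0.5) {
      j <- which.max(zi)
      s <- enc[[i]][j:(j + w - 1)]
      keep <- !is.na(s)
      sc <- sum(log_odds[cbind(s[keep], which(keep))])
      llr <- llr + sc
      site_list[[i]] <- c(start = j, score = sc)
    }
  }
  list(pwm = pwm, gamma = gamma, loglik = ll_trace[length(ll_trace)],
       ll_trace = ll_trace, llr = llr, sites = site_list, width = w)
}

tabulate_weighted <- function(idx, wts) {
  out <- numeric(20)
  for (u in unique(idx)) out[u] <- sum(wts[idx == u])
  out
}

seed_pwms <- function(enc, w, bg, n_seeds = 10, seed_prob = 0.7) {
  # every distinct w-mer scored by its best-match residue count summed over
  # sequences; the top-scoring w-mers seed the EM restarts
  win <- lapply(seq_along(enc), function(i) {
    s <- enc[[i]]
    m <- length(s) - w + 1
    if (m < 1) return(NULL)
    mat <- vapply(seq_len(w), function(k) s[k:(k + m - 1)], integer(m))
    if (m == 1) mat <- matrix(mat, nrow = 1)
    list(seq = i, mat = mat)
  })
  win <- Filter(Negate(is.null), win)
  if (!length(win)) stop("all sequences shorter than width ", w)
  W <- do.call(rbind, lapply(win, `[[`, "mat"))
  win_seq <- unlist(lapply(win, function(x) rep(x$seq, nrow(x$mat))))
  keys <- apply(W, 1, paste, collapse = ",")
  uniq <- !duplicated(keys)
  wmer_mat <- W[uniq, , drop = FALSE]
  wmer_key <- keys[uniq]
  sc <- vapply(seq_len(nrow(wmer_mat)), function(r) {
    eq <- W == matrix(wmer_mat[r, ], nrow(W), w, byrow = TRUE)
    hits <- rowSums(eq, na.rm = TRUE)
    sum(vapply(split(hits, win_seq), max, 0))
  }, 0)
  top <- order(-sc, wmer_key)[seq_len(min(n_seeds, nrow(wmer_mat)))]
  lapply(top, function(r) {
    v <- wmer_mat[r, ]
    pwm <- matrix(rep(bg * (1 - seed_prob), w), 20, w)
    for (k in seq_len(w)) {
      if (!is.na(v[k])) pwm[v[k], k] <- pwm[v[k], k] + seed_prob
      else pwm[, k] <- bg
    }
    sweep(pwm, 2, colSums(pwm), "/")
  })
}

fit_width <- function(enc, w, bg, n_seeds = 10, gamma0 = 0.8, max_iter = 100) {
  seeds <- seed_pwms(enc, w, bg, n_seeds)
  fits <- lapply(seeds, function(p0) zoops_em(enc, w, p0, bg, gamma0, max_iter = max_iter))
  fits[[which.max(vapply(fits, `[[`, 0, "llr"))]]
}

#' Discover motifs with a ZOOPS EM model
#'
#' MEME-style motif discovery under the zero-or-one-occurrence-per-sequence
#' model.  For every candidate width, EM is restarted from the
#' highest-scoring distinct w-mers in the data; the width is chosen by a
#' BIC-penalized log-likelihood-ratio objective so that widths are
#' comparable.  A motif is only emitted when its objective exceeds the
#' empirical null obtained by refitting on within-sequence shuffles
#' (\code{n_shuffles} composition-preserving shuffles; significance when the
#' observed objective is more than \code{z_min} null standard deviations above
#' the null mean).  Accepted sites are masked and the search repeats up to
#' \code{n_motifs}.  Fully reproducible under a fixed seed.
#'
#' @param seqs character vector of at least 2 non-empty sequences.
#' @param wmin,wmax candidate motif width range.
#' @param n_motifs maximum number of motifs to report.
#' @param seed integer seed.
#' @param n_shuffles shuffled-null replicates.
#' @param z_min significance threshold in null standard deviations.
#' @param ids optional sequence ids (default seq1..seqN).
#' @return list of \code{motif_model} objects, each with pwm, width,
#'   background, per-sequence sites, information content and llr.
#' @export
find_motifs <- function(seqs, wmin = 8, wmax = 22, n_motifs = 2, seed = 1,
                        n_shuffles = 100, z_min = 3, ids = NULL) {
  if (length(seqs) < 2) stop("need at least 2 sequences")
  if (any(!nzchar(seqs))) stop("sequences must be non-empty")
  if (wmin > wmax) stop("wmin must be <= wmax")
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  enc <- encode_aa(seqs)
  if (max(vapply(enc, length, 0L)) < wmin)
    stop("all sequences shorter than wmin")
  set.seed(as.integer(seed))
  bg <- zoops_background(enc)
  motifs <- list()
  work <- enc
  for (round in seq_len(n_motifs)) {
    widths <- seq(wmin, wmax)
    widths <- widths[vapply(widths, function(w)
      sum(vapply(work, length, 0L) >= w) >= 2, TRUE)]
    if (!length(widths)) break
    fits <- lapply(widths, function(w) fit_width(work, w, bg))
    # BIC-style penalty keeps the objective comparable across widths
    n_used <- length(work)
    penal <- vapply(fits, function(f) f$llr - 0.5 * 19 * f$width * log(n_used), 0)
    best <- fits[[which.max(penal)]]
    # empirical shuffle null at the chosen width (skipped when disabled)
    if (n_shuffles >= 2 && is.finite(z_min)) {
      null_llr <- vapply(seq_len(n_shuffles), function(b) {
        shuf <- lapply(work, function(s) s[sample.int(length(s))])
        fit_width(shuf, best$width, bg, n_seeds = 3, max_iter = 30)$llr
      }, 0)
      zscore <- (best$llr - mean(null_llr)) / max(stats::sd(null_llr), 1e-9)
      if (!is.finite(zscore) || zscore < z_min) break
    } else {
      zscore <- NA_real_
    }
    motifs[[length(motifs) + 1]] <-
      motif_model(best, bg, ids, zscore = zscore)
    # mask accepted sites (set to NA = background-neutral) and continue
    for (i in seq_along(work)) {
      st <- best$sites[[i]]
      if (!is.null(st))
        work[[i]][st["start"]:(st["start"] + best$width - 1)] <- NA
    }
  }
  motifs
}

motif_model <- function(fit, bg, ids, zscore = NA_real_) {
  pwm <- fit$pwm
  rownames(pwm) <- AA_ALPHABET
  ic <- sum(apply(pwm, 2, function(p) sum(p * log2(p / bg))))
  sites <- data.frame(id = ids,
                      start = vapply(fit$sites, function(s)
                        if (is.null(s)) NA_integer_ else as.integer(s["start"]), 0L),
                      score = vapply(fit$sites, function(s)
                        if (is.null(s)) NA_real_ else unname(s["score"]), 0),
                      stringsAsFactors = FALSE)
  structure(list(width = fit$width, pwm = pwm, background = bg,
                 sites = sites, information_content = ic,
                 llr = fit$llr, gamma = fit$gamma, zscore = zscore,
                 consensus = paste(AA_ALPHABET[apply(pwm, 2, which.max)],
                                   collapse = "")),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif_model: width %d, consensus %s\n", x$width, x$consensus))
  cat(sprintf("  llr %.1f, IC %.1f bits, gamma %.2f, %d/%d sequences with a site\n",
              x$llr, x$information_content, x$gamma,
              sum(!is.na(x$sites$start)), nrow(x$sites)))
  invisible(x)
}

#' Sequences lacking a motif
#'
#' Scans each sequence with the motif's log-odds matrix and reports the ids
#' whose best site score falls below the threshold — the "exceptions/missing"
#' members of an orthogroup motif.
#'
#' @param model \code{motif_model}.
#' @param seqs named character vector (names = ids) or data.frame (id, sequence).
#' @param threshold minimum acceptable best-site log-odds score.
#' @return character vector of exception ids.
#' @export
motif_exceptions <- function(model, seqs, threshold = 0) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$sequence, seqs$id)
  enc <- encode_aa(seqs)
  w <- model$width
  log_odds <- log(model$pwm) - matrix(log(model$background), 20, w)
  best <- vapply(enc, function(s) {
    m <- length(s) - w + 1
    if (m < 1) return(-Inf)
    max(vapply(seq_len(m), function(j) {
      seg <- s[j:(j + w - 1)]
      keep <- !is.na(seg)
      sum(log_odds[cbind(seg[keep], which(keep))])
    }, 0))
  }, 0)
  names(seqs)[best < threshold]
}

#' Export motifs in MEME minimal text format
#'
#' @param motifs list of \code{motif_model}.
#' @param path output file.
#' @param names optional motif names.
#' @return \code{path}, invisibly.
#' @export
write_meme <- function(motifs, path, names = NULL) {
  if (is.null(names)) names <- paste0("MOTIF_", seq_along(motifs))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACDEFGHIKLMNPQRSTVWY", ""), con)
  bg <- motifs[[1]]$background
  ord <- match(sort(AA_ALPHABET), AA_ALPHABET)
  writeLines("Background letter frequencies", con)
  writeLines(paste(sprintf("%s %.6f", AA_ALPHABET[ord], bg[ord]), collapse = " "), con)
  for (k in seq_along(motifs)) {
    m <- motifs[[k]]
    writeLines(c("", paste("MOTIF", names[k]),
                 sprintf("letter-probability matrix: alength= 20 w= %d nsites= %d",
                         m$width, sum(!is.na(m$sites$start)))), con)
    for (j in seq_len(m$width))
      writeLines(paste(sprintf("%.6f", m$pwm[ord, j]), collapse = " "), con)
  }
  invisible(path)
}
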