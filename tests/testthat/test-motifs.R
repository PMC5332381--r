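planted_set <- function(n = 12, len = 60, motif = "WKRHLDNEQTYFPAM",
                        skip = integer(0), mut = 0, seed = 51) {
  set.seed(seed)
  w <- nchar(motif)
  truth <- integer(n)
  seqs <- vapply(seq_len(n), function(i) {
    s <- random_protein(len)
    if (i %in% skip) return(s)
    pos <- sample(seq_len(len - w + 1 - 5), 1)
    m <- strsplit(motif, "")[[1]]
    hit <- runif(w) < mut
    m[hit] <- sample(ogfamily:::AA_ALPHABET, sum(hit), replace = TRUE)
    substr(s, pos, pos + w - 1) <- paste(m, collapse = "")
    truth[i] <<- pos
    s
  }, "")
  list(seqs = seqs, truth = truth, ids = paste0("seq", seq_len(n)))
}

test_that("N-terminal extraction slices before the domain start", {
  r <- protein_records("g1", "Vv", strrep("MKTAY", 100), domain_start = 200)
  expect_equal(extract_nterm(r), substr(r$sequence, 1, 199))
  r2 <- protein_records("g2", "Vv", "MKTAY", domain_start = 1)
  expect_warning(nt <- extract_nterm(r2), "empty N-terminal")
  expect_equal(nt, "")
  r3 <- protein_records("g3", "Vv", "MKTAY")
  expect_error(extract_nterm(r3), "no domain_start")
})

test_that("anchor-estimated domain starts are close to the simulated truth", {
  sim <- simulate_dataset(sim_config(seed = 52))
  ok <- 0; total <- 0
  for (og in unique(sim$records$og_id)[1:10]) {
    rows <- sim$records[sim$records$og_id == og, ]
    if (nrow(rows) < 4) next
    m <- msa(rows$id, rows$sequence)
    sel <- select_blocks(m)
    if (!length(sel$kept_columns)) next
    est <- anchor_domain_start(m, sel)
    total <- total + nrow(rows)
    ok <- ok + sum(abs(est - rows$domain_start) <= 5)
  }
  expect_gte(ok / total, 0.9)
})

test_that("ZOOPS EM keeps valid probability columns and a monotone objective", {
  ps <- planted_set(seed = 53)
  enc <- ogfamily:::encode_aa(ps$seqs)
  bg <- ogfamily:::zoops_background(enc)
  seeds <- ogfamily:::seed_pwms(enc, 15, bg, n_seeds = 3)
  for (p0 in seeds) {
    fit <- ogfamily:::zoops_em(enc, 15, p0, bg)
    expect_true(all(abs(colSums(fit$pwm) - 1) < 1e-9))
    expect_true(all(fit$pwm > 0))
    expect_true(all(diff(fit$ll_trace) > -1e-6 * pmax(1, abs(fit$ll_trace[-length(fit$ll_trace)]))))
  }
})

test_that("a planted motif is recovered with the right width and sites", {
  ps <- planted_set(mut = 0.1, seed = 54)
  ms <- find_motifs(ps$seqs, wmin = 12, wmax = 18, n_motifs = 1, seed = 5,
                    ids = ps$ids)
  expect_length(ms, 1)
  m <- ms[[1]]
  expect_lte(abs(m$width - 15), 2)
  hits <- m$sites[!is.na(m$sites$start), ]
  recall <- mean(abs(hits$start - ps$truth[match(hits$id, ps$ids)]) <= 2)
  expect_gte(recall, 0.9)
})

test_that("identical copies of one sequence give a degenerate high-IC motif", {
  seqs <- rep("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEV", 6)
  ms <- find_motifs(seqs, wmin = 10, wmax = 12, n_motifs = 1, seed = 6,
                    n_shuffles = 30)
  expect_length(ms, 1)
  starts <- ms[[1]]$sites$start
  expect_length(unique(starts[!is.na(starts)]), 1)
  expect_gt(ms[[1]]$information_content / ms[[1]]$width, 3)
})

test_that("motif discovery is bit-identical under the same seed", {
  ps <- planted_set(seed = 55)
  m1 <- find_motifs(ps$seqs, wmin = 14, wmax = 16, n_motifs = 1, seed = 9,
                    n_shuffles = 20)
  m2 <- find_motifs(ps$seqs, wmin = 14, wmax = 16, n_motifs = 1, seed = 9,
                    n_shuffles = 20)
  expect_identical(m1, m2)
})

test_that("input contracts are enforced", {
  expect_error(find_motifs("MKT", wmin = 2, wmax = 4), "at least 2")
  expect_error(find_motifs(c("MKT", "MAV"), wmin = 10, wmax = 12), "shorter")
  expect_error(find_motifs(c("MKT", "MAV"), wmin = 4, wmax = 2), "wmin")
})

test_that("motif exceptions are exactly the sequences lacking the planted site", {
  ps <- planted_set(skip = c(3, 7), seed = 56)
  ms <- find_motifs(ps$seqs, wmin = 14, wmax = 16, n_motifs = 1, seed = 10,
                    ids = ps$ids)
  expect_length(ms, 1)
  exc <- motif_exceptions(ms[[1]], setNames(ps$seqs, ps$ids), threshold = 8)
  expect_setequal(exc, c("seq3", "seq7"))
  # threshold above any attainable score returns every id
  max_score <- sum(apply(log(ms[[1]]$pwm) - log(ms[[1]]$background), 2, max))
  exc_all <- motif_exceptions(ms[[1]], setNames(ps$seqs, ps$ids),
                              threshold = max_score + 1)
  expect_setequal(exc_all, ps$ids)
  # exact consensus instances everywhere -> no exceptions
  ps0 <- planted_set(mut = 0, seed = 57)
  ms0 <- find_motifs(ps0$seqs, wmin = 15, wmax = 15, n_motifs = 1, seed = 11,
                     n_shuffles = 30, ids = ps0$ids)
  expect_length(motif_exceptions(ms0[[1]], setNames(ps0$seqs, ps0$ids),
                                 threshold = 8), 0)
})

test_that("planted-site recall degrades monotonically with mutation rate", {
  rates <- c(0, 0.15, 0.35, 0.6)
  recalls <- vapply(rates, function(r) {
    hit <- vapply(1:5, function(s) {
      ps <- planted_set(mut = r, seed = 600 + 17 * s + round(100 * r))
      ms <- find_motifs(ps$seqs, wmin = 15, wmax = 15, n_motifs = 1,
                        seed = s, n_shuffles = 0, z_min = -Inf, ids = ps$ids)
      hits <- ms[[1]]$sites
      mean(!is.na(hits$start) & abs(hits$start - ps$truth) <= 2)
    }, 0)
    mean(hit)
  }, 0)
  expect_true(all(diff(recalls) <= 0.05 + 1e-9))
  expect_gt(recalls[1], recalls[length(recalls)])
})

test_that("MEME minimal export is well formed", {
  ps <- planted_set(seed = 58)
  ms <- find_motifs(ps$seqs, wmin = 15, wmax = 15, n_motifs = 1, seed = 12,
                    n_shuffles = 20)
  f <- withr::local_tempfile(fileext = ".txt")
  write_meme(ms, f, names = "PLANTED")
  lines <- readLines(f)
  expect_true(any(grepl("^MEME version", lines)))
  expect_true(any(grepl("^MOTIF PLANTED", lines)))
  mat <- grep("letter-probability", lines)
  vals <- strsplit(lines[mat + 1], " ")[[1]]
  expect_length(vals, 20)
  expect_equal(sum(as.numeric(vals)), 1, tolerance = 1e-3)
})
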