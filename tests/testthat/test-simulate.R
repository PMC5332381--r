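test_that("the no-event limit yields one gene per root gene and species", {
  sim <- simulate_dataset(sim_config(duplication_rate = 0, loss_rate = 0, seed = 71))
  expect_equal(nrow(sim$records), 29 * 8)
  expect_true(all(sim$truth$count_matrix == 1L))
  expect_equal(dim(sim$truth$count_matrix), c(29L, 8L))
})

test_that("simulation is bit-reproducible under a fixed seed", {
  s1 <- simulate_dataset(sim_config(seed = 72))
  s2 <- simulate_dataset(sim_config(seed = 72))
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth, s2$truth)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_protein_fasta(s1$records, f1)
  write_protein_fasta(s2$records, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("ground-truth matrix matches the emitted records", {
  sim <- simulate_dataset(sim_config(seed = 73))
  for (og in rownames(sim$truth$count_matrix)) {
    for (sp in colnames(sim$truth$count_matrix)) {
      n <- sum(sim$records$og_id == og & sim$records$species == sp)
      expect_equal(unname(sim$truth$count_matrix[og, sp]), n)
    }
  }
})

test_that("per-branch survival frequency matches the analytic expectation", {
  # single branch of length t: survival of a lossy lineage ~ exp(-lambda t)
  tree <- ape::read.tree(text = "((A:2,B:2)ab:0.001,C:2.001)root;")
  reg <- species_registry(c("A", "B", "C"), c("a", "b", "c"),
                         c("monocot", "dicot", "basal"),
                         c("oA", "oB", "oC"), c("fA", "fB", "fC"))
  lambda <- 0.3
  cfg <- sim_config(species_tree = tree, registry = reg, n_root_genes = 170,
                    duplication_rate = 0, loss_rate = lambda, hot_og = NA,
                    nterm_length_range = c(5, 8), domain_length_range = c(10, 14),
                    seed = 74)
  sim <- simulate_dataset(cfg)
  surv <- mean(sim$truth$count_matrix[, "A"] > 0)
  p <- exp(-lambda * 2.001)
  se <- sqrt(p * (1 - p) / cfg$n_root_genes)
  expect_lt(abs(surv - p), 3 * se + 1e-9)
})

test_that("sequences do not change on zero-length branches", {
  cfg <- sim_config(seed = 75)
  s <- strrep("MKTAYIAKQR", 4)
  region <- rep(c("nterm", "domain"), each = 20)
  out <- evolve_sequence(s, 0, region, cfg)
  expect_identical(out$sequence, s)
})

test_that("substitution counts match the small-branch analytic rate", {
  cfg <- sim_config(seed = 76)
  set.seed(76)
  t <- 0.02
  s <- paste(rep("A", 500), collapse = "")
  region <- rep("domain", 500)
  diffs <- vapply(1:200, function(i) {
    out <- evolve_sequence(s, t, region, cfg)
    mean(strsplit(out$sequence, "")[[1]] != "A")
  }, 0)
  # domain multiplier 0.5; expected changed fraction ~ 1 - exp(-r t) with the
  # LG rate for alanine
  e <- ogfamily:::lg_eigen()
  S <- matrix(0, 20, 20); S[lower.tri(S)] <- ogfamily:::LG_EXCHANGE; S <- S + t(S)
  Q <- S * rep(ogfamily:::LG_FREQS, each = 20); diag(Q) <- -rowSums(Q)
  Q <- Q / sum(-diag(Q) * ogfamily:::LG_FREQS)
  r <- -Q[1, 1] * cfg$domain_rate_multiplier
  expected <- 1 - exp(-r * t)
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - expected), 3 * se + 5e-4)
})

test_that("the N-terminus diverges faster than the domain", {
  cfg <- sim_config(seed = 77)
  set.seed(77)
  wins <- vapply(1:60, function(i) {
    nt <- paste(sample(ogfamily:::AA_ALPHABET, 50, TRUE), collapse = "")
    dm <- paste(sample(ogfamily:::AA_ALPHABET, 50, TRUE), collapse = "")
    s <- paste0(nt, dm)
    region <- rep(c("nterm", "domain"), each = 50)
    out <- evolve_sequence(s, 0.4, region, cfg)$sequence
    d_nt <- mean(strsplit(substr(out, 1, 50), "")[[1]] != strsplit(nt, "")[[1]])
    d_dm <- mean(strsplit(substr(out, 51, 100), "")[[1]] != strsplit(dm, "")[[1]])
    d_nt > d_dm
  }, TRUE)
  expect_gte(mean(wins), 0.95)
})

test_that("forced clade losses empty every sampled species of the clade", {
  cfg <- sim_config(seed = 78,
                    clade_loss_table = data.frame(root_gene = c(3, 7),
                                                  clade = c("Brassicales", "monocots")))
  sim <- simulate_dataset(cfg)
  expect_equal(unname(sim$truth$count_matrix["ROG03", "At"]), 0L)
  expect_true(all(sim$truth$count_matrix["ROG07", c("Os", "Pd", "Ma")] == 0L))
  expect_true(any(sim$truth$events$type == "forced-clade-loss"))
})

test_that("the elevated-duplication OG is usually the largest", {
  wins <- vapply(1:25, function(s) {
    sim <- simulate_dataset(sim_config(seed = 900 + s))
    tot <- rowSums(sim$truth$count_matrix)
    names(which.max(tot)) == "ROG29"
  }, TRUE)
  expect_gte(mean(wins), 0.9)
})

test_that("motif planting respects carriers, windows and bookkeeping", {
  spec <- data.frame(root_gene = 1, motif = "WKRHLDNEQTYFPAM",
                     window_min = 1, window_max = 10,
                     mutation_prob = 0, carrier_fraction = 1)
  cfg <- sim_config(seed = 79, duplication_rate = 0, loss_rate = 0,
                    motif_spec = spec)
  sim <- simulate_dataset(cfg)
  members <- sim$records[sim$records$og_id == "ROG01", ]
  expect_true(all(grepl("WKRHLDNEQTYFPAM", members$sequence, fixed = TRUE)))
  expect_null(sim$truth$motif_exceptions)
  expect_equal(nrow(sim$truth$motif_sites), nrow(members))
  expect_true(all(sim$truth$motif_sites$start <= 10))

  spec$carrier_fraction <- 10 / 12
  cfg2 <- sim_config(seed = 80, duplication_rate = 0, loss_rate = 0,
                     motif_spec = spec)
  sim2 <- simulate_dataset(cfg2)
  n_members <- sum(sim2$records$og_id == "ROG01")
  expect_equal(nrow(sim2$truth$motif_exceptions),
               n_members - round(10 / 12 * n_members))
})

test_that("oversized motifs and degenerate trees are rejected", {
  spec <- data.frame(root_gene = 1, motif = strrep("W", 100),
                     window_min = 1, window_max = 5,
                     mutation_prob = 0, carrier_fraction = 1)
  cfg <- sim_config(seed = 81, motif_spec = spec)
  expect_error(simulate_dataset(cfg), "longer than")
  star <- ape::read.tree(text = "(Amb:1,Vv:1,Os:1);")
  expect_error(simulate_dataset(sim_config(species_tree = star, seed = 82)),
               "binary")
  expect_error(sim_config(nterm_rate_multiplier = 0.4,
                          domain_rate_multiplier = 0.5), "faster")
})
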