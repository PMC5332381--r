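test_that("fully conserved gap-free alignments keep a single spanning block", {
  m <- msa(c("s1", "s2", "s3"), rep(strrep("MKTAYIAKQR", 3), 3))
  sel <- select_blocks(m)
  expect_equal(nrow(sel$blocks), 1)
  expect_equal(sel$kept_columns, 1:30)
})

test_that("gap policy controls whether gappy conserved columns survive", {
  # column 11 conserved among residues but 60% gapped
  core <- strrep("MKTAYIAKQR", 2)
  rows <- c(paste0(substr(core, 1, 10), "W", substr(core, 11, 20)),
            paste0(substr(core, 1, 10), "W", substr(core, 11, 20)),
            paste0(substr(core, 1, 10), "-", substr(core, 11, 20)),
            paste0(substr(core, 1, 10), "-", substr(core, 11, 20)),
            paste0(substr(core, 1, 10), "-", substr(core, 11, 20)))
  m <- msa(paste0("s", 1:5), rows)
  sel_none <- select_blocks(m, gap_policy = "none", max_nonconserved_run = 0,
                            min_block_length = 3)
  sel_all <- select_blocks(m, gap_policy = "all")
  expect_false(11 %in% sel_none$kept_columns)
  expect_true(11 %in% sel_all$kept_columns)
})

test_that("a planted conserved segment is recovered exactly", {
  set.seed(41)
  n <- 10; len <- 120; start <- 51; width <- 20
  conserved <- random_protein(width)
  rows <- vapply(seq_len(n), function(i) {
    s <- random_protein(len)
    substr(s, start, start + width - 1) <- conserved
    s
  }, "")
  m <- msa(paste0("s", 1:n), rows)
  sel <- select_blocks(m, min_conserved_frac = 0.8, max_nonconserved_run = 3)
  expect_equal(sel$kept_columns, start:(start + width - 1))
})

test_that("raising the conservation threshold never adds kept columns", {
  set.seed(42)
  rows <- vapply(1:8, function(i) {
    s <- random_protein(80)
    substr(s, 21, 40) <- "MKTAYIAKQRMKTAYIAKQR"
    substr(s, 61, 70) <- "WWHHRRDDEE"
    s
  }, "")
  m <- msa(paste0("s", 1:8), rows)
  fracs <- c(0.3, 0.5, 0.7, 0.9, 1.0)
  kept <- lapply(fracs, function(f)
    select_blocks(m, min_conserved_frac = f)$kept_columns)
  for (k in seq_along(fracs)[-1])
    expect_true(all(kept[[k]] %in% kept[[k - 1]]),
                info = paste("frac", fracs[k]))
})

test_that("block distances follow the closed forms", {
  m <- msa(c("a", "b"), c("MKTAYIAKQR", "MKTAYIAKQR"))
  sel <- select_blocks(m, min_block_length = 1)
  expect_equal(unname(block_distance(m, sel, "p")["a", "b"]), 0)

  m2 <- msa(c("a", "b"), c("AAAAAAAAAA", "AAAAACCCCC"))
  d_p <- block_distance(m2, 1:10, "p")
  expect_equal(unname(d_p["a", "b"]), 0.5)
  d_pois <- block_distance(m2, 1:10, "poisson")
  expect_equal(unname(d_pois["a", "b"]), -log(0.5), tolerance = 1e-12)
  expect_error(block_distance(msa(c("a", "b"), c("A-", "-A")), 1:2), "comparable")
})

test_that("distance matrices are symmetric with zero diagonal on random inputs", {
  set.seed(43)
  for (k in 1:5) {
    rows <- vapply(1:6, function(i) random_protein(40), "")
    m <- msa(paste0("s", 1:6), rows)
    d <- block_distance(m, 1:40, "p")
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0))
  }
})

test_that("three-taxon trees use the exact three-point formulas", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  pl <- ape::cophenetic.phylo(tr)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(unname(pl), unname(d), tolerance = 1e-12)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("NJ inverts random additive matrices exactly (topology and lengths)", {
  for (seed in 1:8) {
    n <- sample(4:10, 1)
    gen <- random_additive(n, seed + 100)
    tr <- nj_tree(gen$d)
    # patristic distances reproduce the generating matrix exactly
    got <- ape::cophenetic.phylo(tr)[rownames(gen$d), colnames(gen$d)]
    expect_equal(got, gen$d, tolerance = 1e-8)
    # topology identical to the generating tree
    expect_equal(ape::dist.topo(ape::unroot(gen$tree), tr), 0,
                 ignore_attr = TRUE)
    # and agrees with the independent ape implementation
    expect_equal(ape::dist.topo(ape::nj(gen$d), tr), 0, ignore_attr = TRUE)
  }
})

test_that("bootstrap supports are deterministic and sane", {
  sim <- simulate_dataset(sim_config(seed = 44))
  og <- sim$records[sim$records$og_id == "ROG02", ]
  m <- msa(og$id, og$sequence)
  sel <- select_blocks(m)
  b1 <- bootstrap_support(m, sel, n_replicates = 30, seed = 7)
  b2 <- bootstrap_support(m, sel, n_replicates = 30, seed = 7)
  expect_identical(attr(b1, "support"), attr(b2, "support"))
  expect_true(all(attr(b1, "support") >= 0 & attr(b1, "support") <= 1))
})

test_that("bootstrap supports are invariant to leaf order", {
  sim <- simulate_dataset(sim_config(seed = 45))
  og <- sim$records[sim$records$og_id == "ROG03", ]
  m1 <- msa(og$id, og$sequence)
  perm <- rev(seq_along(og$id))
  m2 <- msa(og$id[perm], og$sequence[perm])
  sel1 <- select_blocks(m1); sel2 <- select_blocks(m2)
  s1 <- attr(bootstrap_support(m1, sel1, 25, seed = 9), "support")
  s2 <- attr(bootstrap_support(m2, sel2, 25, seed = 9), "support")
  expect_setequal(names(s1), names(s2))
  expect_equal(s1[sort(names(s1))], s2[sort(names(s1))])
})

test_that("clean well-separated data yields full support for true splits", {
  # additive tree with long internal branches, sequences evolved on it
  sim <- simulate_dataset(sim_config(seed = 46, duplication_rate = 0,
                                     loss_rate = 0, n_root_genes = 1))
  og <- sim$records
  m <- msa(og$id, og$sequence)
  sel <- select_blocks(m)
  bt <- bootstrap_support(m, sel, n_replicates = 100, seed = 3)
  sup <- attr(bt, "support")
  # species-tree splits among the 8 single-copy genes are strongly supported
  expect_gte(mean(sup >= 0.9), 0.6)
  expect_true(all(sup > 0))
})

test_that("monophyly checking matches brute-force edge enumeration", {
  set.seed(47)
  for (k in 1:10) {
    n <- sample(5:12, 1)
    tree <- ape::rtree(n, rooted = FALSE)
    labels <- setNames(sample(LETTERS[1:3], n, replace = TRUE), tree$tip.label)
    rep <- check_og_monophyly(tree, labels)
    for (og in rep$og_id) {
      members <- names(labels)[labels == og]
      expect_equal(rep$consistent[rep$og_id == og],
                   oracle_monophyletic(tree, members),
                   info = paste("seed", k, "og", og))
    }
  }
})

test_that("a swapped leaf splits both orthogroups and is identified", {
  tree <- ape::read.tree(text = "(((a1:1,a2:1):1,b1:1):1,((b2:1,b3:1):1,a3:1):1);")
  labels <- setNames(c("A", "A", "B", "B", "B", "A"),
                     c("a1", "a2", "b1", "b2", "b3", "a3"))
  rep <- check_og_monophyly(tree, labels)
  expect_false(rep$consistent[rep$og_id == "A"])
  expect_false(rep$consistent[rep$og_id == "B"])
  expect_equal(rep$offending[rep$og_id == "A"], "a3")
  expect_equal(rep$offending[rep$og_id == "B"], "b1")
  expect_error(check_og_monophyly(tree, labels[-1]), "unlabeled")
})

test_that("the LBA probe stays quiet on clean data and errors on tiny trees", {
  sim <- simulate_dataset(sim_config(seed = 48, duplication_rate = 0,
                                     loss_rate = 0, n_root_genes = 1))
  m <- msa(sim$records$id, sim$records$sequence)
  rep <- lba_probe(m, focal_id = sim$records$id[sim$records$species == "Amb"])
  expect_false(rep$lba_flag)
  m4 <- msa(m$ids[1:4], m$rows[1:4])
  expect_error(lba_probe(m4, focal_id = m4$ids[1]), "fewer than 4")
  expect_error(lba_probe(m, focal_id = "nope"), "not present")
})

test_that("rate-accelerated lineages trigger the LBA flag in most replicates", {
  flags <- vapply(1:10, function(s) {
    cfg <- sim_config(seed = 400 + s, duplication_rate = 0, loss_rate = 0,
                      n_root_genes = 1)
    sim <- simulate_dataset(cfg)
    recs <- sim$records
    set.seed(4000 + s)
    # independently accelerate the basal gene and the At gene (5x)
    for (sp in c("Amb", "At")) {
      i <- which(recs$species == sp)
      region <- c(rep("nterm", recs$domain_start[i] - 1),
                  rep("domain", nchar(recs$sequence[i]) - recs$domain_start[i] + 1))
      recs$sequence[i] <- evolve_sequence(recs$sequence[i], 4 * 0.35, region, cfg)$sequence
    }
    m <- msa(recs$id, recs$sequence)
    lba_probe(m, focal_id = recs$id[recs$species == "Amb"])$lba_flag
  }, TRUE)
  expect_gte(mean(flags), 0.8)
})
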