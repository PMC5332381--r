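manual_hit_table <- function(ids, species, scores) {
  dimnames(scores) <- list(ids, ids)
  structure(list(scores = scores, id = ids, species = species),
            class = "hit_table")
}

test_that("reciprocal best pairs require mutual top hits", {
  # two species, one gene each, mutual top hits -> exactly one pair
  sc <- matrix(c(10, 8, 8, 10), 2, 2)
  ht <- manual_hit_table(c("a", "b"), c("Vv", "Os"), sc)
  p <- reciprocal_best_pairs(ht)
  expect_equal(nrow(p), 1)
  expect_equal(sort(unname(unlist(p[1, ]))), c("a", "b"))

  # a's best in Os is b, but b's best in Vv is c != a -> (a,b) excluded
  ids <- c("a", "b", "c")
  sc <- matrix(0, 3, 3)
  sc[1, 2] <- sc[2, 1] <- 5   # a-b
  sc[2, 3] <- sc[3, 2] <- 9   # b-c
  sc[1, 3] <- sc[3, 1] <- 1   # a-c (same species: ignored)
  ht <- manual_hit_table(ids, c("Vv", "Os", "Vv"), sc)
  p <- reciprocal_best_pairs(ht)
  expect_equal(nrow(p), 1)
  expect_equal(sort(unname(unlist(p[1, ]))), c("b", "c"))
})

test_that("single-copy families are fully recovered as reciprocal pairs", {
  sim <- simulate_dataset(sim_config(duplication_rate = 0, loss_rate = 0,
                                     n_root_genes = 5, seed = 21))
  recs <- sim$records
  ht <- hit_table(recs)
  nonbasal <- recs$id[recs$species != "Amb"]
  p <- reciprocal_best_pairs(ht, include = nonbasal)
  og <- sim$truth$og
  expect_true(all(og[p$a] == og[p$b]))
  # every cross-species pair within an OG is a true ortholog pair
  per_og <- table(og[nonbasal])
  expected_pairs <- sum(per_og * (per_og - 1) / 2)  # 7 species, single copy
  expect_equal(nrow(p), expected_pairs)
})

test_that("in-paralog absorption and outgroup attachment follow the rules", {
  base <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQDNLSGAEKAVQVKVKALPDAQ"
  tweak <- function(s, at, to) { substr(s, at, at) <- to; s }
  recs <- protein_records(
    id = c("At_1", "Os_1", "Vv_1", "Vv_2", "Amb_1", "Amb_far"),
    species = c("At", "Os", "Vv", "Vv", "Amb", "Amb"),
    sequence = c(base,
                 tweak(base, 3, "W"),
                 tweak(base, 5, "W"),
                 tweak(tweak(base, 5, "W"), 10, "H"),  # Vv in-paralog
                 tweak(base, 7, "W"),
                 paste(rep("GS", 30), collapse = "")))  # unrelated outgroup gene
  ht <- hit_table(recs)
  ogs <- build_orthogroups(recs, ht, angiosperm_registry())
  a <- ogs$assignments
  expect_equal(length(ogs$og_ids), 1)
  expect_setequal(a$id[a$og_id == ogs$og_ids[1]],
                  c("At_1", "Os_1", "Vv_1", "Vv_2", "Amb_1"))
  expect_equal(a$provenance[a$id == "Vv_2"], "in-paralog")
  expect_equal(a$provenance[a$id == "Amb_1"], "outgroup-attach")
  expect_true(a$provenance[a$id == "At_1"] == "rbh")
  expect_equal(ogs$unassigned, "Amb_far")  # no reciprocity: stays unassigned
})

test_that("zero-rate simulation yields a perfect 29-OG partition", {
  sim <- simulate_dataset(sim_config(duplication_rate = 0, loss_rate = 0, seed = 22))
  expect_equal(nrow(sim$records), 29 * 8)
  ht <- hit_table(sim$records)
  ogs <- build_orthogroups(sim$records, ht, angiosperm_registry())
  expect_equal(length(ogs$og_ids), 29)
  expect_equal(ari(sim$truth$og[ogs$assignments$id], ogs$assignments$og_id), 1.0)
})

test_that("orthogroup inference is a deterministic partition of the gene set", {
  sim <- simulate_dataset(sim_config(seed = 23))
  ht <- hit_table(sim$records)
  reg <- angiosperm_registry()
  o1 <- build_orthogroups(sim$records, ht, reg)
  o2 <- build_orthogroups(sim$records, ht, reg)
  expect_identical(o1$assignments, o2$assignments)
  # partition: no gene twice, assigned + unassigned = all genes
  expect_false(anyDuplicated(o1$assignments$id) > 0)
  expect_setequal(c(o1$assignments$id, o1$unassigned), sim$records$id)
})

test_that("anchor-split validation and empty inputs raise errors", {
  sim <- simulate_dataset(sim_config(n_root_genes = 3, seed = 24))
  ht <- hit_table(sim$records)
  tax <- load_tax()
  expect_error(build_orthogroups(sim$records, ht, angiosperm_registry(),
                                 tax = tax, anchor = c("monocots", "asterids")),
               "anchor split absent")
  expect_error(build_orthogroups(sim$records[0, ], ht, angiosperm_registry()),
               "empty")
})

test_that("manual overrides are honoured last with manual provenance", {
  sim <- simulate_dataset(sim_config(n_root_genes = 3,
                                     duplication_rate = 0, loss_rate = 0, seed = 25))
  ht <- hit_table(sim$records)
  g <- sim$records$id[1]
  ogs <- build_orthogroups(sim$records, ht, angiosperm_registry(),
                           manual_overrides = data.frame(id = g, og_id = "OG-CUSTOM"))
  a <- ogs$assignments
  expect_equal(a$og_id[a$id == g], "OG-CUSTOM")
  expect_equal(a$provenance[a$id == g], "manual")
})

test_that("deleting a species never merges previously disjoint cores", {
  sim <- simulate_dataset(sim_config(seed = 26))
  reg <- angiosperm_registry()
  full <- build_orthogroups(sim$records, hit_table(sim$records), reg)
  keep <- sim$records$species != "Tc"
  reduced_recs <- sim$records[keep, ]
  class(reduced_recs) <- class(sim$records)
  reduced <- build_orthogroups(reduced_recs, hit_table(reduced_recs), reg)
  fa <- full$assignments; ra <- reduced$assignments
  core <- intersect(fa$id[fa$provenance == "rbh"], ra$id[ra$provenance == "rbh"])
  f_of <- setNames(fa$og_id, fa$id)[core]
  r_of <- setNames(ra$og_id, ra$id)[core]
  # reduced cores refine full cores: same reduced OG -> same full OG
  for (og in unique(r_of))
    expect_length(unique(f_of[r_of == og]), 1)
})

test_that("reference members classify back to their own orthogroup", {
  sim <- simulate_dataset(sim_config(n_root_genes = 6, seed = 27))
  recs <- sim$records
  recs$og_id <- unname(sim$truth$og[recs$id])
  picks <- seq(1, nrow(recs), by = 4)
  for (i in picks) {
    res <- classify_query(recs[i, ], recs)
    expect_equal(res$og_id, recs$og_id[i])
    expect_true(res$reciprocal_ok)
    expect_gte(res$margin, 0)
  }
})

test_that("novel-lineage queries classify correctly; shuffled queries do not", {
  sim <- simulate_dataset(sim_config(seed = 28))
  recs <- sim$records
  recs$og_id <- unname(sim$truth$og[recs$id])
  cfg <- sim_config(seed = 28)
  set.seed(280)
  picks <- sample(nrow(recs), 10)
  correct <- 0
  for (i in picks) {
    region <- c(rep("nterm", recs$domain_start[i] - 1),
                rep("domain", nchar(recs$sequence[i]) - recs$domain_start[i] + 1))
    ev <- evolve_sequence(recs$sequence[i], 0.25, region, cfg)
    q <- protein_records("newsp_q", "Cc", ev$sequence)
    res <- classify_query(q, recs)
    if (res$og_id == recs$og_id[i]) correct <- correct + 1
  }
  expect_gte(correct, 9)

  shuf <- paste(sample(strsplit(recs$sequence[1], "")[[1]]), collapse = "")
  res <- classify_query(protein_records("shuf_q", "Cc", shuf), recs)
  expect_equal(res$og_id, "unassigned")
  expect_error(classify_query(recs[1, ], recs[0, ]), "empty")
})
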