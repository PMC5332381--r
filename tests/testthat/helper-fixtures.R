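# Shared fixtures and independent oracles for the test suite.

table1_path <- function() system.file("extdata", "table1_counts.tsv", package = "ogfamily")
evidence_path <- function() system.file("extdata", "table1_evidence.tsv", package = "ogfamily")
taxonomy_path <- function() system.file("extdata", "species_tree.nwk", package = "ogfamily")

load_table1 <- function() read_count_matrix(table1_path())
load_tax <- function() read_taxonomy(taxonomy_path(), angiosperm_registry())

random_protein <- function(n, alphabet = ogfamily:::AA_ALPHABET) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# a small integer scoring scheme over a reduced alphabet for oracle tests
toy_scheme <- function(match = 3, mismatch = -2, gap_open = 4, gap_extend = 1) {
  ab <- c("A", "C", "G", "T")
  m <- matrix(mismatch, 4, 4, dimnames = list(ab, ab))
  diag(m) <- match
  scoring_scheme(m, gap_open = gap_open, gap_extend = gap_extend)
}

# ---- exhaustive alignment oracles ---------------------------------------
# Enumerate every monotone alignment path explicitly, tracking the affine gap
# state; completely independent of the DP implementation.  Gap of length L
# costs open + (L - 1) * extend.

oracle_global <- function(a, b, scheme) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  la <- length(ca); lb <- length(cb)
  open <- scheme$gap_open; ext <- scheme$gap_extend
  mat <- scheme$matrix
  best <- -Inf
  rec <- function(i, j, state, acc) {
    if (i > la && j > lb) {
      if (acc > best) best <<- acc
      return(invisible())
    }
    if (i <= la && j <= lb)
      rec(i + 1, j + 1, "m", acc + mat[ca[i], cb[j]])
    if (j <= lb)   # gap in a, consume b[j]
      rec(i, j + 1, "ga", acc - if (state == "ga") ext else open)
    if (i <= la)   # gap in b, consume a[i]
      rec(i + 1, j, "gb", acc - if (state == "gb") ext else open)
  }
  rec(1, 1, "m", 0)
  best
}

oracle_local <- function(a, b, scheme) {
  la <- nchar(a); lb <- nchar(b)
  best <- 0
  for (i1 in seq_len(la)) for (i2 in i1:la) {
    sa <- substr(a, i1, i2)
    for (j1 in seq_len(lb)) for (j2 in j1:lb) {
      sc <- oracle_global(sa, substr(b, j1, j2), scheme)
      if (sc > best) best <- sc
    }
  }
  best
}

# brute-force clade check: an OG is monophyletic iff some edge bipartition
# side equals its leaf set; enumerate every edge of the unrooted tree
oracle_monophyletic <- function(tree, members) {
  tips <- tree$tip.label
  ntip <- length(tips)
  if (length(members) <= 1 || length(members) == ntip) return(TRUE)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    side <- if (child <= ntip) tips[child] else
      tips[ogfamily:::leaf_descendants(tree, child)]
    if (setequal(side, members) || setequal(setdiff(tips, side), members))
      return(TRUE)
  }
  FALSE
}

# random additive distance matrix: random topology + positive branch lengths,
# distances from the generating tree's path lengths
random_additive <- function(n, seed) {
  set.seed(seed)
  tree <- ape::rtree(n, rooted = FALSE)
  tree$edge.length <- runif(nrow(tree$edge), 0.5, 3)
  d <- ape::cophenetic.phylo(tree)
  list(tree = tree, d = d[sort(rownames(d)), sort(rownames(d))])
}

ari <- function(x, y) mclust::adjustedRandIndex(x, y)

# deterministic toy records: two species, simple sequences
toy_records <- function() {
  protein_records(
    id = c("g1", "g2", "g3", "g4"),
    species = c("Vv", "Vv", "Os", "Os"),
    sequence = c("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
                 "MNPQRSTVWYACDEFGHIKL",
                 "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVA",
                 "MNPQRSTVWYACDEFGHIKM"))
}
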