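#' Simulation configuration for synthetic gene families
#'
#' The generator emulates the statistical structure a gene-family
#' classification pipeline assumes: a species tree with a basal outgroup and a
#' monocot/dicot split, per-gene birth-death duplication and loss along
#' branches, optional forced clade-wide losses, two-region proteins with a
#' slow conserved C-terminal domain and a fast hypervariable N-terminus
#' (LG substitution model, region-specific rate multipliers), and plantable
#' OG-specific N-terminal motifs.  One root gene may carry an elevated
#' duplication rate, mimicking a family's one strongly expanding orthogroup.
#'
#' @param species_tree phylo tree with branch lengths; default the packaged
#'   eight-species angiosperm topology with the basal outgroup.
#' @param registry \code{species_registry} matching the tree leaves.
#' @param n_root_genes ancestral genes at the root (default 29).
#' @param duplication_rate,loss_rate events per gene per unit branch length.
#' @param hot_og index of the root gene with elevated duplication (NA for
#'   none); \code{hot_multiplier} scales its duplication rate.
#' @param clade_loss_table optional data.frame (root_gene, clade): after the
#'   stochastic events, all genes of that root gene are deleted from the
#'   clade's species.
#' @param nterm_length_range,domain_length_range residue-length ranges of the
#'   two regions, sampled uniformly per root gene.
#' @param nterm_rate_multiplier,domain_rate_multiplier substitution-rate
#'   multipliers (N-terminus must be faster).
#' @param motif_spec optional data.frame (root_gene, motif, window_min,
#'   window_max, mutation_prob, carrier_fraction) of motifs to plant.
#' @param p_tandem probability a duplication is labelled tandem (vs segmental)
#'   in the event log.
#' @param indel_rate N-terminal indel events per residue per unit branch
#'   length (geometric lengths; 0 disables length drift).
#' @param seed integer seed.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(species_tree = NULL, registry = angiosperm_registry(),
                       n_root_genes = 29, duplication_rate = 0.1,
                       loss_rate = 0.15, hot_og = n_root_genes,
                       hot_multiplier = 15, clade_loss_table = NULL,
                       nterm_length_range = c(30, 60),
                       domain_length_range = c(110, 150),
                       nterm_rate_multiplier = 3,
                       domain_rate_multiplier = 0.5,
                       motif_spec = NULL, p_tandem = 0.5, indel_rate = 0,
                       seed = 1) {
  if (is.null(species_tree)) species_tree <- default_species_tree()
  if (!inherits(species_tree, "phylo")) stop("species_tree must be a phylo object")
  if (is.null(species_tree$edge.length)) stop("species tree must have branch lengths")
  if (duplication_rate < 0 || loss_rate < 0) stop("rates must be >= 0")
  if (nterm_rate_multiplier <= domain_rate_multiplier)
    stop("the N-terminus must evolve faster than the domain")
  structure(list(species_tree = species_tree, registry = registry,
                 n_root_genes = n_root_genes,
                 duplication_rate = duplication_rate, loss_rate = loss_rate,
                 hot_og = hot_og, hot_multiplier = hot_multiplier,
                 clade_loss_table = clade_loss_table,
                 nterm_length_range = nterm_length_range,
                 domain_length_range = domain_length_range,
                 nterm_rate_multiplier = nterm_rate_multiplier,
                 domain_rate_multiplier = domain_rate_multiplier,
                 motif_spec = motif_spec, p_tandem = p_tandem,
                 indel_rate = indel_rate, seed = seed),
            class = "sim_config")
}

#' Default eight-species tree used by the simulator
#' @return phylo tree with named internal clades and branch lengths.
#' @export
default_species_tree <- function() {
  ape::read.tree(text = paste0(
    "(((Os:0.6,(Pd:0.4,Ma:0.4):0.2)monocots:0.3,",
    "((Vv:0.5,(Tc:0.35,At:0.35):0.15):0.1,Cc:0.6)dicots:0.3)mesangiosperms:0.3,",
    "Amb:0.9)root;"))
}

# ---- LG substitution machinery ------------------------------------------

lg_eigen <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    S <- matrix(0, 20, 20)
    S[lower.tri(S)] <- LG_EXCHANGE
    S <- S + t(S)
    pi <- LG_FREQS
    Q <- S * rep(pi, each = 20)
    diag(Q) <- -rowSums(Q)
    Q <- Q / sum(-diag(Q) * pi)      # one expected substitution per unit time
    # reversible: symmetrize for a stable eigendecomposition
    sq <- sqrt(pi)
    B <- diag(sq) %*% Q %*% diag(1 / sq)
    e <- eigen((B + t(B)) / 2, symmetric = TRUE)
    cache <<- list(values = e$values,
                   U = diag(1 / sq) %*% e$vectors,
                   Uinv = t(e$vectors) %*% diag(sq),
                   pi = pi)
    cache
  }
})

lg_pmatrix <- function(t) {
  e <- lg_eigen()
  P <- e$U %*% (exp(e$values * t) * e$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Evolve a protein sequence along a branch
#'
#' Per-site substitution under the LG model, with the branch length scaled by
#' a region-specific rate multiplier: the conserved domain evolves slowly and
#' without indels, the N-terminal region fast and (optionally) with geometric
#' length drift.
#'
#' @param seq amino-acid string.
#' @param branch_length non-negative branch length.
#' @param region_map character vector (\code{"nterm"}/\code{"domain"}) per
#'   residue.
#' @param config \code{sim_config} (rate multipliers and indel rate).
#' @return list(sequence, region_map): the map is returned because N-terminal
#'   indels change the region boundaries.
#' @export
evolve_sequence <- function(seq, branch_length, region_map, config) {
  if (branch_length < 0) stop("branch_length must be >= 0")
  s <- match(strsplit(seq, "")[[1]], AA_ALPHABET)
  if (length(s) != length(region_map)) stop("region_map length mismatch")
  if (branch_length == 0)
    return(list(sequence = seq, region_map = region_map))
  for (region in c("nterm", "domain")) {
    idx <- which(region_map == region)
    if (!length(idx)) next
    mult <- if (region == "nterm") config$nterm_rate_multiplier else
      config$domain_rate_multiplier
    P <- lg_pmatrix(branch_length * mult)
    old <- s[idx]
    new <- old
    for (r in unique(old)) {
      sel <- which(old == r)
      new[sel] <- sample.int(20, length(sel), replace = TRUE, prob = P[r, ])
    }
    s[idx] <- new
  }
  # optional N-terminal length drift
  if (config$indel_rate > 0) {
    nt <- which(region_map == "nterm")
    n_ev <- stats::rpois(1, config$indel_rate * branch_length * length(nt))
    for (k in seq_len(n_ev)) {
      nt <- which(region_map == "nterm")
      if (length(nt) < 2) break
      len <- stats::rgeom(1, 0.5) + 1
      if (runif(1) < 0.5) {  # insertion
        pos <- sample(nt, 1)
        ins <- sample.int(20, len, replace = TRUE, prob = LG_FREQS)
        s <- append(s, ins, after = pos)
        region_map <- append(region_map, rep("nterm", len), after = pos)
      } else {               # deletion
        pos <- sample(nt, 1)
        del <- pos:min(pos + len - 1, max(nt))
        s <- s[-del]
        region_map <- region_map[-del]
      }
    }
  }
  list(sequence = paste(AA_ALPHABET[s], collapse = ""), region_map = region_map)
}

#' Simulate a synthetic gene-family dataset with ground truth
#'
#' Each root gene evolves down the species tree under a branchwise
#' birth-death process (exponential waiting times; duplications fork the
#' lineage, losses kill it), sequences evolve along the resulting gene trees,
#' forced clade losses are applied after the stochastic events, and motifs
#' are planted when configured.  Bit-reproducible under a fixed seed.
#'
#' @param config \code{sim_config}.
#' @return list of class \code{sim_result} with \code{records}
#'   (\code{protein_records}) and \code{truth}: gene -> root OG map, true
#'   count matrix, true gene trees (newick), per-gene domain starts, event
#'   log, motif sites and motif exceptions.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tree <- config$species_tree
  if (any(tabulate(tree$edge[, 1]) > 2)) stop("species tree must be binary")
  set.seed(as.integer(config$seed))
  tax <- taxonomy(tree, config$registry)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  children <- function(v) tree$edge[tree$edge[, 1] == v, 2]
  edge_len <- function(v) tree$edge.length[tree$edge[, 2] == v]
  node_name <- function(v) if (v <= ntip) tree$tip.label[v] else
    tree$node.label[v - ntip]

  events <- list()
  genes <- list()
  counter <- new.env()

  for (g in seq_len(config$n_root_genes)) {
    og <- sprintf("ROG%02d", g)
    nl <- sample(seq(config$nterm_length_range[1], config$nterm_length_range[2]), 1)
    dl <- sample(seq(config$domain_length_range[1], config$domain_length_range[2]), 1)
    region <- c(rep("nterm", nl), rep("domain", dl))
    rootseq <- paste(AA_ALPHABET[sample.int(20, nl + dl, replace = TRUE,
                                            prob = LG_FREQS)], collapse = "")
    dup_rate <- config$duplication_rate *
      if (!is.na(config$hot_og) && g == config$hot_og) config$hot_multiplier else 1

    sim_lineage <- function(seq, region_map, node, t_left, elapsed) {
      total <- dup_rate + config$loss_rate
      dt <- if (total > 0) rexp(1, total) else Inf
      if (dt >= t_left) {
        ev <- evolve_sequence(seq, t_left, region_map, config)
        if (node <= ntip) {
          sp <- tree$tip.label[node]
          k <- get0(sp, envir = counter, inherits = FALSE, ifnotfound = 0L) + 1L
          assign(sp, k, envir = counter)
          id <- sprintf("%s_g%03d", sp, k)
          genes[[length(genes) + 1]] <<- list(
            id = id, species = sp, sequence = ev$sequence, og = og,
            domain_start = sum(ev$region_map == "nterm") + 1L)
          return(list(newick = id, rootlen = elapsed + t_left))
        }
        kids <- children(node)
        res <- lapply(kids, function(ch)
          sim_lineage(ev$sequence, ev$region_map, ch, edge_len(ch), 0))
        res <- Filter(Negate(is.null), res)
        if (!length(res)) return(NULL)
        if (length(res) == 1)
          return(list(newick = res[[1]]$newick,
                      rootlen = elapsed + t_left + res[[1]]$rootlen))
        return(list(
          newick = sprintf("(%s:%.6f,%s:%.6f)", res[[1]]$newick, res[[1]]$rootlen,
                           res[[2]]$newick, res[[2]]$rootlen),
          rootlen = elapsed + t_left))
      }
      ev <- evolve_sequence(seq, dt, region_map, config)
      if (runif(1) < config$loss_rate / total) {
        events[[length(events) + 1]] <<- list(og = og, branch = node_name(node),
                                              type = "loss")
        return(NULL)
      }
      dtype <- if (runif(1) < config$p_tandem) "tandem" else "segmental"
      events[[length(events) + 1]] <<- list(og = og, branch = node_name(node),
                                            type = paste0("duplication-", dtype))
      r1 <- sim_lineage(ev$sequence, ev$region_map, node, t_left - dt, 0)
      r2 <- sim_lineage(ev$sequence, ev$region_map, node, t_left - dt, 0)
      res <- Filter(Negate(is.null), list(r1, r2))
      if (!length(res)) return(NULL)
      if (length(res) == 1)
        return(list(newick = res[[1]]$newick,
                    rootlen = elapsed + dt + res[[1]]$rootlen))
      list(newick = sprintf("(%s:%.6f,%s:%.6f)", res[[1]]$newick, res[[1]]$rootlen,
                            res[[2]]$newick, res[[2]]$rootlen),
           rootlen = elapsed + dt)
    }

    kids <- children(root)
    res <- lapply(kids, function(ch)
      sim_lineage(rootseq, region, ch, edge_len(ch), 0))
    res <- Filter(Negate(is.null), res)
    gt <- if (!length(res)) NA_character_ else if (length(res) == 1)
      paste0(res[[1]]$newick, ";") else
      sprintf("(%s:%.6f,%s:%.6f);", res[[1]]$newick, res[[1]]$rootlen,
              res[[2]]$newick, res[[2]]$rootlen)
    if (g == 1) gene_trees <- character(0)
    gene_trees[og] <- gt
  }

  ids <- vapply(genes, `[[`, "", "id")
  og_map <- setNames(vapply(genes, `[[`, "", "og"), ids)
  species <- vapply(genes, `[[`, "", "species")
  seqs <- vapply(genes, `[[`, "", "sequence")
  dstart <- vapply(genes, function(x) as.integer(x$domain_start), 0L)

  # forced clade-wide losses
  if (!is.null(config$clade_loss_table)) {
    drop <- rep(FALSE, length(ids))
    for (k in seq_len(nrow(config$clade_loss_table))) {
      og <- sprintf("ROG%02d", config$clade_loss_table$root_gene[k])
      clade_sp <- resolve_clade(tax, config$clade_loss_table$clade[k])
      hit <- og_map[ids] == og & species %in% clade_sp
      drop <- drop | hit
      events[[length(events) + 1]] <- list(og = og,
                                           branch = config$clade_loss_table$clade[k],
                                           type = "forced-clade-loss")
    }
    ids <- ids[!drop]; species <- species[!drop]; seqs <- seqs[!drop]
    dstart <- dstart[!drop]; og_map <- og_map[ids]
  }

  og_levels <- sprintf("ROG%02d", seq_len(config$n_root_genes))
  truth_matrix <- table(factor(og_map[ids], levels = og_levels),
                        factor(species, levels = config$registry$code))
  truth_matrix <- matrix(as.integer(truth_matrix), length(og_levels),
                         nrow(config$registry),
                         dimnames = list(og_levels, config$registry$code))

  records <- protein_records(ids, species, seqs, status = "valid",
                             domain_start = dstart, og_id = og_map[ids],
                             registry = config$registry)
  truth <- list(og = og_map, count_matrix = truth_matrix,
                gene_trees = gene_trees, domain_start = setNames(dstart, ids),
                events = if (length(events))
                  do.call(rbind, lapply(events, as.data.frame)) else NULL,
                motif_sites = NULL, motif_exceptions = NULL)
  out <- list(records = records, truth = truth, config = config)
  class(out) <- "sim_result"

  if (!is.null(config$motif_spec)) out <- plant_motif(out, config$motif_spec)
  out
}

#' @export
print.sim_result <- function(x, ...) {
  cat("sim_result:", nrow(x$records), "genes in",
      length(unique(x$records$species)), "species,",
      x$config$n_root_genes, "root genes\n")
  invisible(x)
}

#' Plant orthogroup-specific N-terminal motifs
#'
#' Copies each configured motif into the N-terminus of a random carrier
#' fraction of its orthogroup's genes, at a uniform-random offset within the
#' window, mutating each motif site independently with the stated
#' probability.  Non-carriers are recorded as ground-truth exceptions.
#'
#' @param sim \code{sim_result}.
#' @param motif_spec data.frame (root_gene, motif, window_min, window_max,
#'   mutation_prob, carrier_fraction).
#' @return updated \code{sim_result} with motif sites/exceptions in the truth.
#' @export
plant_motif <- function(sim, motif_spec) {
  records <- sim$records
  sites <- list()
  exceptions <- list()
  for (k in seq_len(nrow(motif_spec))) {
    og <- sprintf("ROG%02d", motif_spec$root_gene[k])
    motif <- toupper(motif_spec$motif[k])
    w <- nchar(motif)
    members <- which(records$og_id == og)
    if (!length(members)) next
    avail <- records$domain_start[members] - w
    if (any(avail < 1))
      stop("motif longer than the available N-terminal window for ", og)
    n_carry <- round(motif_spec$carrier_fraction[k] * length(members))
    carriers <- sort(sample(members, n_carry))
    for (i in carriers) {
      lo <- max(1L, motif_spec$window_min[k])
      hi <- min(records$domain_start[i] - w, motif_spec$window_max[k])
      if (hi < lo) stop("motif window empty for ", records$id[i])
      pos <- if (hi > lo) sample(lo:hi, 1) else lo
      m <- strsplit(motif, "")[[1]]
      mut <- runif(w) < motif_spec$mutation_prob[k]
      m[mut] <- AA_ALPHABET[sample.int(20, sum(mut), replace = TRUE)]
      s <- strsplit(records$sequence[i], "")[[1]]
      s[pos:(pos + w - 1)] <- m
      records$sequence[i] <- paste(s, collapse = "")
      sites[[length(sites) + 1]] <- data.frame(id = records$id[i], og = og,
                                               start = pos, width = w,
                                               stringsAsFactors = FALSE)
    }
    for (i in setdiff(members, carriers))
      exceptions[[length(exceptions) + 1]] <- data.frame(id = records$id[i],
                                                         og = og,
                                                         stringsAsFactors = FALSE)
  }
  sim$records <- records
  sim$truth$motif_sites <- if (length(sites)) do.call(rbind, sites) else NULL
  sim$truth$motif_exceptions <- if (length(exceptions))
    do.call(rbind, exceptions) else NULL
  sim
}
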