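#' Species registry
#'
#' A registry records, for every species code used in sequence headers, the
#' full species name, its lineage class (\code{basal}, \code{monocot} or
#' \code{dicot}), and its order and family.  Order and family names double as
#' single-species clade labels when losses are called against lineages that
#' only one sampled species represents (e.g. Brassicales for
#' \emph{A. thaliana}).  Exactly one species may be flagged \code{basal}: the
#' outgroup used to polarize orthogroup ancestry.
#'
#' @param code character vector of short species codes (unique).
#' @param full_name character vector of species names.
#' @param lineage one of \code{"basal"}, \code{"monocot"}, \code{"dicot"} per species.
#' @param order_name,family_name taxonomic order and family per species.
#' @return A data.frame of class \code{species_registry}.
#' @examples
#' reg <- angiosperm_registry()
#' reg$code
#' @export
species_registry <- function(code, full_name, lineage, order_name, family_name) {
  stopifnot(length(code) == length(full_name), length(code) == length(lineage),
            length(code) == length(order_name), length(code) == length(family_name))
  if (anyDuplicated(code)) stop("species codes must be unique")
  lineage <- match.arg(lineage, c("basal", "monocot", "dicot"), several.ok = TRUE)
  if (sum(lineage == "basal") > 1) stop("at most one species may be flagged basal")
  out <- data.frame(code = as.character(code), full_name = as.character(full_name),
                    lineage = lineage, order_name = as.character(order_name),
                    family_name = as.character(family_name), stringsAsFactors = FALSE)
  class(out) <- c("species_registry", "data.frame")
  out
}

#' Default eight-species angiosperm panel
#'
#' The panel used throughout the package examples: three monocots
#' (\emph{Musa acuminata}, \emph{Phoenix dactylifera}, \emph{Oryza sativa}),
#' four dicots (\emph{Vitis vinifera}, \emph{Theobroma cacao},
#' \emph{Arabidopsis thaliana}, \emph{Coffea canephora}) and
#' \emph{Amborella trichopoda} as the basal outgroup.
#'
#' @return A \code{species_registry}.
#' @export
angiosperm_registry <- function() {
  species_registry(
    code        = c("Amb", "Ma", "Pd", "Os", "Vv", "Tc", "At", "Cc"),
    full_name   = c("Amborella trichopoda", "Musa acuminata", "Phoenix dactylifera",
                    "Oryza sativa", "Vitis vinifera", "Theobroma cacao",
                    "Arabidopsis thaliana", "Coffea canephora"),
    lineage     = c("basal", "monocot", "monocot", "monocot",
                    "dicot", "dicot", "dicot", "dicot"),
    order_name  = c("Amborellales", "Zingiberales", "Arecales", "Poales",
                    "Vitales", "Malvales", "Brassicales", "Gentianales"),
    family_name = c("Amborellaceae", "Musaceae", "Arecaceae", "Poaceae",
                    "Vitaceae", "Malvaceae", "Brassicaceae", "Rubiaceae"))
}

#' Basal (outgroup) species of a registry
#' @param registry a \code{species_registry}.
#' @return The basal species code, or \code{NA_character_} if none is flagged.
#' @export
basal_species <- function(registry) {
  b <- registry$code[registry$lineage == "basal"]
  if (length(b) == 0) NA_character_ else b
}

#' Read a species taxonomy from a Newick file
#'
#' The taxonomy is a rooted tree whose leaves are species codes; internal
#' nodes may carry clade labels (e.g. \code{monocots}, \code{dicots}).  When a
#' registry is given the leaf set must match its codes exactly.
#'
#' @param path Newick file.
#' @param registry optional \code{species_registry} to validate leaves against.
#' @return An object of class \code{taxonomy} wrapping an \code{ape} phylo tree.
#' @export
read_taxonomy <- function(path, registry = NULL) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("malformed Newick in ", path, ": ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("malformed Newick in ", path)
  taxonomy(tree, registry)
}

#' Construct a taxonomy from an ape phylo tree
#'
#' @param tree an \code{ape} phylo object, leaves labelled with species codes.
#' @param registry optional registry; leaf set must equal its codes.
#' @return A \code{taxonomy}: list with the tree, a clade-name to leaf-set
#'   index (tree internal labels plus, if a registry is given, order and
#'   family groupings and the single-species "clades").
#' @export
taxonomy <- function(tree, registry = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object")
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels in taxonomy")
  if (!is.null(registry)) {
    if (!setequal(tree$tip.label, registry$code))
      stop("taxonomy leaf set does not match registry codes")
  }
  clades <- list()
  # levels order the specificity of same-leafset clades: species < family <
  # order < tree node (used to narrow or widen loss calls deterministically)
  levels <- numeric(0)
  if (!is.null(tree$node.label)) {
    labs <- tree$node.label
    nonempty <- which(!is.na(labs) & labs != "")
    if (anyDuplicated(labs[nonempty])) stop("duplicate clade names in taxonomy")
    ntip <- length(tree$tip.label)
    for (k in nonempty) {
      node <- ntip + k
      tips <- leaf_descendants(tree, node)
      clades[[labs[k]]] <- sort(tree$tip.label[tips])
      levels[labs[k]] <- 3
    }
  }
  if (!is.null(registry)) {
    for (fam in unique(registry$family_name)) {
      if (!fam %in% names(clades)) {
        clades[[fam]] <- sort(registry$code[registry$family_name == fam])
        levels[fam] <- 1
      }
    }
    for (ord in unique(registry$order_name)) {
      if (!ord %in% names(clades)) {
        clades[[ord]] <- sort(registry$code[registry$order_name == ord])
        levels[ord] <- 2
      }
    }
  }
  for (sp in tree$tip.label) {
    if (!sp %in% names(clades)) {
      clades[[sp]] <- sp
      levels[sp] <- 0
    }
  }
  structure(list(tree = tree, clades = clades, levels = levels,
                 registry = registry),
            class = "taxonomy")
}

# tip indices below an internal node
leaf_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  sort(out)
}

#' Resolve a clade label to its sampled species
#'
#' @param tax a \code{taxonomy}.
#' @param clade a clade name: a tree internal label, an order or family name
#'   from the registry, or a species code.
#' @return Character vector of species codes inside the clade.
#' @export
resolve_clade <- function(tax, clade) {
  stopifnot(inherits(tax, "taxonomy"))
  if (!clade %in% names(tax$clades))
    stop("unknown clade: ", clade)
  tax$clades[[clade]]
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("Taxonomy over", length(x$tree$tip.label), "species;",
      length(x$clades), "resolvable clades\n")
  invisible(x)
}
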