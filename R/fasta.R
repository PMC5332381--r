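AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")

#' Construct a set of protein records
#'
#' The central sequence container: one row per curated protein, carrying the
#' species code, the amino-acid sequence (20-letter alphabet plus X), a
#' curation status (\code{valid}, \code{pseudogene} or \code{remnant}), an
#' optional 1-based start of the conserved C-terminal domain, and an optional
#' orthogroup label.
#'
#' @param id unique gene identifiers.
#' @param species species codes.
#' @param sequence amino-acid strings.
#' @param status per-record status; recycled. Valid records must have a
#'   non-empty sequence.
#' @param domain_start optional 1-based index of the conserved domain start.
#' @param og_id optional orthogroup labels.
#' @param registry optional \code{species_registry}; species codes are
#'   validated against it when given.
#' @return data.frame of class \code{protein_records}.
#' @export
protein_records <- function(id, species, sequence, status = "valid",
                            domain_start = NA_integer_, og_id = NA_character_,
                            registry = NULL) {
  n <- length(id)
  status <- rep_len(status, n)
  domain_start <- rep_len(as.integer(domain_start), n)
  og_id <- rep_len(as.character(og_id), n)
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate record ids: ", paste(head(dup, 5), collapse = ", "))
  }
  if (!all(status %in% c("valid", "pseudogene", "remnant")))
    stop("status must be one of valid, pseudogene, remnant")
  sequence <- toupper(as.character(sequence))
  sequence <- sub("\\*+$", "", sequence)   # trailing stop symbols
  bad <- grepl(sprintf("[^%sX]", paste(AA_ALPHABET, collapse = "")), sequence)
  if (any(bad))
    stop("residues outside the amino-acid alphabet in: ",
         paste(head(id[bad], 5), collapse = ", "))
  empty_valid <- status == "valid" & nchar(sequence) == 0
  if (any(empty_valid))
    stop("valid-status records must have non-empty sequences: ",
         paste(head(id[empty_valid], 5), collapse = ", "))
  ds_bad <- !is.na(domain_start) & (domain_start < 1 | domain_start > nchar(sequence))
  if (any(ds_bad))
    stop("domain_start out of range for: ", paste(head(id[ds_bad], 5), collapse = ", "))
  if (!is.null(registry)) {
    unknown <- setdiff(unique(species), registry$code)
    if (length(unknown))
      stop("unknown species code(s): ", paste(unknown, collapse = ", "))
  }
  out <- data.frame(id = as.character(id), species = as.character(species),
                    sequence = sequence, status = status,
                    domain_start = domain_start, og_id = og_id,
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_records", "data.frame")
  out
}

#' @export
print.protein_records <- function(x, ...) {
  cat("protein_records:", nrow(x), "records,",
      length(unique(x$species)), "species\n")
  tab <- table(x$status)
  cat(" status:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read species-coded protein FASTA
#'
#' Headers follow the \code{"SPECIES|gene"} convention (delimiter
#' configurable); the full header up to the first whitespace is parsed.  A
#' species map can override the parsed species codes for supplementary files
#' whose headers vary by source genome.
#'
#' @param path FASTA file.
#' @param registry optional registry for species-code validation.
#' @param delim header delimiter between species code and gene id.
#' @param species_map optional data.frame (id, species) overriding parsed codes.
#' @return \code{protein_records}. Sequences are uppercased and trailing
#'   \code{*} stop symbols stripped.
#' @export
read_protein_fasta <- function(path, registry = NULL, delim = "|", species_map = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) {
    warning("empty FASTA file: ", path)
    return(protein_records(character(0), character(0), character(0)))
  }
  headers <- sub("\\s.*$", "", names(aa))
  parts <- strsplit(headers, delim, fixed = TRUE)
  species <- vapply(parts, function(p) if (length(p) >= 2) p[[1]] else NA_character_, "")
  ids <- vapply(parts, function(p) if (length(p) >= 2) paste(p[-1], collapse = delim) else p[[1]], "")
  if (anyNA(species))
    stop("headers not in SPECIES", delim, "gene form: ",
         paste(head(headers[is.na(species)], 3), collapse = ", "))
  if (!is.null(species_map)) {
    idx <- match(ids, species_map$id)
    species[!is.na(idx)] <- species_map$species[idx[!is.na(idx)]]
  }
  protein_records(ids, species, as.character(aa), registry = registry)
}

#' Write protein records as species-coded FASTA
#'
#' @param records \code{protein_records}.
#' @param path output file.
#' @param delim header delimiter.
#' @return \code{path}, invisibly.
#' @export
write_protein_fasta <- function(records, path, delim = "|") {
  seqs <- Biostrings::AAStringSet(records$sequence)
  names(seqs) <- paste(records$species, records$id, sep = delim)
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}
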