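# seq_io: codon alignment and manifest input, validation, concatenation.

#' Construct a codon alignment
#'
#' Validates in-frame codon structure: equal sequence lengths, length a
#' multiple of 3, residues restricted to `{A,C,G,T,N,-}`. Any codon column
#' containing a gap or `N` in any sequence is masked for all computations
#' (complete deletion at codon granularity). A terminal stop codon is trimmed;
#' an internal stop codon in an unmasked column is an error naming the
#' sequence and the 1-based codon index.
#'
#' @param sequences character vector of aligned DNA sequences.
#' @param ids sequence identifiers (default `names(sequences)`).
#' @param genome genome type: `"mitochondrial"`, `"nuclear"` or
#'   `"chloroplast"`.
#' @param genetic_code one of `"standard"`, `"vertebrate_mitochondrial"`,
#'   `"invertebrate_mitochondrial"`, `"plant_plastid"`. Default `NULL` picks
#'   the NCBI convention for `genome` (`vertebrate_mitochondrial` for
#'   mitochondrial, `plant_plastid` for chloroplast, `standard` otherwise).
#' @return an object of class `codon_alignment` with elements `ids`, `seq`
#'   (post-trim sequences), `codons` (integer matrix, one row per sequence,
#'   `NA` marking ambiguous codons), `masked` (logical per codon column),
#'   `n_codons`, `length_nt`, `genome`, `genetic_code`.
#' @export
codon_alignment <- function(sequences, ids = names(sequences),
                            genome = "nuclear", genetic_code = NULL) {
  if (length(sequences) < 1L) stop("alignment needs at least one sequence")
  genome <- check_enum(genome, GENOME_TYPES, "genome")
  if (is.null(genetic_code)) genetic_code <- default_genetic_code(genome)
  genetic_code <- check_enum(genetic_code, GENETIC_CODES, "genetic_code")
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate sequence ids in alignment")

  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("alignment error: ragged sequence lengths (",
         paste(unique(lens), collapse = ", "), ")")
  if (lens[1] %% 3L != 0L)
    stop("frame error: alignment length ", lens[1], " is not a multiple of 3")
  if (lens[1] == 0L) stop("alignment has zero length")

  cod <- t(vapply(sequences, dna_to_codons, integer(lens[1] %/% 3L)))
  if (nrow(cod) != length(sequences)) cod <- matrix(cod, nrow = length(sequences))
  tbl <- codon_table(genetic_code)

  # trim a terminal stop column (any sequence having a stop there)
  last <- ncol(cod)
  last_stop <- !is.na(cod[, last]) & tbl$is_stop[cod[, last]]
  if (any(last_stop)) {
    cod <- cod[, -last, drop = FALSE]
    sequences <- substr(sequences, 1L, (last - 1L) * 3L)
    if (ncol(cod) == 0L) stop("alignment has no codons left after stop trim")
  }

  masked <- apply(cod, 2L, anyNA)
  # internal stops in unmasked columns are frame/code errors
  for (j in which(!masked)) {
    st <- tbl$is_stop[cod[, j]]
    if (any(st))
      stop(sprintf(
        "internal stop codon in sequence '%s' at codon %d under the %s code",
        ids[which(st)[1]], j, genetic_code))
  }

  structure(list(ids = ids, seq = unname(as.character(sequences)),
                 codons = unname(cod), masked = unname(masked),
                 n_codons = ncol(cod), length_nt = ncol(cod) * 3L,
                 genome = genome, genetic_code = genetic_code),
            class = "codon_alignment")
}

#' Default genetic code for a genome type
#'
#' NCBI conventions: vertebrate mitochondrial code for mitochondrial
#' alignments, plastid (bacterial) code for chloroplast, standard otherwise.
#' For invertebrate mitochondrial data pass
#' `genetic_code = "invertebrate_mitochondrial"` explicitly (or set it in the
#' manifest).
#'
#' @param genome genome type string.
#' @return genetic code name.
#' @export
default_genetic_code <- function(genome) {
  switch(check_enum(genome, GENOME_TYPES, "genome"),
         mitochondrial = "vertebrate_mitochondrial",
         chloroplast = "plant_plastid",
         "standard")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment: %d sequence(s) x %d codons (%d nt), %s, %s code; %d masked codon(s)\n",
              length(x$ids), x$n_codons, x$length_nt, x$genome,
              x$genetic_code, sum(x$masked)))
  invisible(x)
}

#' Read a codon alignment from FASTA
#'
#' @param path FASTA file (wrapped or unwrapped, multi-record).
#' @inheritParams codon_alignment
#' @return a [codon_alignment].
#' @export
read_codon_alignment <- function(path, genetic_code = NULL,
                                 genome = "nuclear") {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  codon_alignment(as.character(ss), ids = names(ss), genome = genome,
                  genetic_code = genetic_code)
}

#' Write a codon alignment to FASTA
#'
#' @param aln a [codon_alignment].
#' @param path output file.
#' @param width line width for wrapping (default 20000 writes one line per
#'   record, which keeps read/write round trips byte-stable for typical
#'   alignment lengths).
#' @return `path`, invisibly.
#' @export
write_codon_alignment <- function(aln, path, width = 20000L) {
  stopifnot(inherits(aln, "codon_alignment"))
  ss <- Biostrings::DNAStringSet(setNames(aln$seq, aln$ids))
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

#' Concatenate codon alignments of the same species set
#'
#' Codon-wise concatenation preserving per-locus masking. All inputs must
#' share the same genome tag, genetic code and species (id) set; sequences
#' are matched by id, in the order of the first alignment.
#'
#' @param alignments list of [codon_alignment] objects.
#' @return one [codon_alignment] with `length_nt` equal to the sum of inputs.
#' @export
concatenate_loci <- function(alignments) {
  if (!length(alignments)) stop("no alignments to concatenate")
  if (length(alignments) == 1L) return(alignments[[1]])
  ref <- alignments[[1]]
  for (a in alignments[-1]) {
    if (a$genome != ref$genome)
      stop("mixed genome tags: ", ref$genome, " vs ", a$genome)
    if (a$genetic_code != ref$genetic_code)
      stop("mixed genetic codes: ", ref$genetic_code, " vs ", a$genetic_code)
    if (!setequal(a$ids, ref$ids))
      stop("mismatched species sets across loci")
  }
  seqs <- vapply(ref$ids, function(id) {
    paste0(vapply(alignments,
                  function(a) a$seq[match(id, a$ids)], ""), collapse = "")
  }, "")
  codon_alignment(seqs, ids = ref$ids, genome = ref$genome,
                  genetic_code = ref$genetic_code)
}

.MANIFEST_REQUIRED <- c("comparison_id", "island_species", "mainland_species",
                        "outgroup_species", "genome", "taxon_group",
                        "direction")
.MANIFEST_OPTIONAL <- c("island_range_km2", "mainland_range_km2",
                        "polymorphism_files", "divergence_file",
                        "genetic_code", "group_id")

.split_list <- function(x, sep = ",") {
  if (is.na(x) || !nzchar(x)) return(character())
  trimws(strsplit(x, sep, fixed = TRUE)[[1]])
}

.parse_range <- function(x, col, id) {
  if (is.na(x) || !nzchar(trimws(x))) return(NA_real_)
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v) || v < 0)
    stop(sprintf("validation error in comparison '%s': %s must be a nonnegative number (got '%s')",
                 id, col, x))
  v
}

#' Read a comparison manifest
#'
#' Tab-separated table with a header row. Required columns:
#' `comparison_id`, `island_species`, `mainland_species`, `outgroup_species`
#' (species lists comma-separated), `genome`, `taxon_group`, `direction`.
#' Optional columns: `island_range_km2`, `mainland_range_km2`,
#' `polymorphism_files` (semicolon-separated `species=path` entries; a
#' species may appear several times for multiple loci), `divergence_file`,
#' `genetic_code`, `group_id` (groups alternative-genome rows of the same
#' biological comparison for the longest-alignment selection rule; defaults
#' to `comparison_id`). Unknown columns are ignored with a warning. Missing
#' optional fields are `NA`, never zero.
#'
#' @param path manifest TSV.
#' @return a list of manifest entries, class `comparison_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   check.names = FALSE, quote = "", comment.char = "#")
  miss <- setdiff(.MANIFEST_REQUIRED, names(df))
  if (length(miss))
    stop("manifest is missing required column(s): ", paste(miss, collapse = ", "))
  unknown <- setdiff(names(df), c(.MANIFEST_REQUIRED, .MANIFEST_OPTIONAL))
  if (length(unknown))
    warning("manifest: ignoring unknown column(s): ",
            paste(unknown, collapse = ", "))
  if (anyDuplicated(df$comparison_id))
    stop("duplicate comparison_id: ",
         paste(unique(df$comparison_id[duplicated(df$comparison_id)]),
               collapse = ", "))

  opt <- function(row, col) if (col %in% names(df)) df[[col]][row] else NA_character_

  entries <- lapply(seq_len(nrow(df)), function(i) {
    id <- df$comparison_id[i]
    island <- .split_list(df$island_species[i])
    mainland <- .split_list(df$mainland_species[i])
    if (!length(island) || !length(mainland))
      stop(sprintf("comparison '%s': at least one island and one mainland species required", id))
    genome <- check_enum(df$genome[i], GENOME_TYPES,
                         sprintf("genome (comparison '%s')", id))
    taxon <- check_enum(df$taxon_group[i], TAXON_GROUPS,
                        sprintf("taxon_group (comparison '%s')", id))
    direction <- check_enum(df$direction[i], DIRECTIONS,
                            sprintf("direction (comparison '%s')", id))
    code <- opt(i, "genetic_code")
    code <- if (is.na(code) || !nzchar(code)) default_genetic_code(genome)
            else check_enum(code, GENETIC_CODES,
                            sprintf("genetic_code (comparison '%s')", id))
    poly_raw <- opt(i, "polymorphism_files")
    poly <- list()
    if (!is.na(poly_raw) && nzchar(poly_raw)) {
      parts <- .split_list(poly_raw, ";")
      kv <- strsplit(parts, "=", fixed = TRUE)
      if (any(lengths(kv) != 2L))
        stop(sprintf("comparison '%s': polymorphism_files entries must be species=path", id))
      for (p in kv) poly[[p[1]]] <- c(poly[[p[1]]], p[2])
    }
    dv <- opt(i, "divergence_file")
    if (!is.na(dv) && !nzchar(dv)) dv <- NA_character_
    grp <- opt(i, "group_id")
    if (is.na(grp) || !nzchar(grp)) grp <- id
    structure(list(
      comparison_id = id, group_id = grp,
      island_species = island, mainland_species = mainland,
      outgroup_species = .split_list(df$outgroup_species[i])[1],
      genome = genome, taxon_group = taxon, direction = direction,
      genetic_code = code,
      island_range_km2 = .parse_range(opt(i, "island_range_km2"),
                                      "island_range_km2", id),
      mainland_range_km2 = .parse_range(opt(i, "mainland_range_km2"),
                                        "mainland_range_km2", id),
      polymorphism_files = poly,
      divergence_file = dv), class = "comparison_entry")
  })
  structure(entries, class = "comparison_manifest")
}

#' Validate a divergence alignment against a manifest entry
#'
#' The divergence alignment must contain exactly one sequence per listed
#' species and equal numbers of island and mainland species (node-density
#' balance).
#'
#' @param aln a [codon_alignment].
#' @param entry one manifest entry.
#' @return `TRUE`, invisibly; errors otherwise.
#' @export
validate_divergence_alignment <- function(aln, entry) {
  species <- c(entry$island_species, entry$mainland_species,
               entry$outgroup_species)
  miss <- setdiff(species, aln$ids)
  if (length(miss))
    stop(sprintf("comparison '%s': divergence alignment lacks sequence(s): %s",
                 entry$comparison_id, paste(miss, collapse = ", ")))
  counts <- table(aln$ids)[species]
  if (any(counts != 1L))
    stop(sprintf("comparison '%s': divergence alignment must have exactly one sequence per species",
                 entry$comparison_id))
  if (length(entry$island_species) != length(entry$mainland_species))
    stop(sprintf("comparison '%s': unequal numbers of island (%d) and mainland (%d) species in divergence data",
                 entry$comparison_id, length(entry$island_species),
                 length(entry$mainland_species)))
  invisible(TRUE)
}
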