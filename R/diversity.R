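# diversity: Nei-Gojobori site counting, pathway-averaged difference
# classification, and within-species nucleotide diversity.

#' Nei-Gojobori fractional site counts for one codon
#'
#' For each of the three positions, the synonymous fraction is the number of
#' the three single-nucleotide mutants that are synonymous divided by the
#' number of non-stop mutants; `syn_sites` is the sum of the fractions and
#' `nonsyn_sites = 3 - syn_sites`.
#'
#' @param codon 3-letter DNA string (no gaps or ambiguity), not a stop.
#' @param genetic_code genetic code name.
#' @return named numeric vector `c(syn_sites, nonsyn_sites)`.
#' @examples
#' count_sites("TGG")  # tryptophan: c(0, 3)
#' count_sites("GGG")  # glycine: c(1, 2)
#' @export
count_sites <- function(codon, genetic_code = "standard") {
  tbl <- codon_table(genetic_code)
  ci <- codon_str_to_index(codon)
  if (is.na(ci)) stop("ambiguous or invalid codon: ", codon)
  if (tbl$is_stop[ci]) stop("stop codon has no site counts: ", codon)
  c(syn_sites = tbl$syn_sites[ci], nonsyn_sites = tbl$nonsyn_sites[ci])
}

#' Classify the differences between two codons
#'
#' Nei-Gojobori pathway averaging: enumerate all orderings of the differing
#' positions, discard orderings that pass through a stop codon, and average
#' the synonymous/non-synonymous step counts over the remaining orderings.
#'
#' @param codon_a,codon_b 3-letter DNA strings, both sense codons.
#' @inheritParams count_sites
#' @return named numeric vector `c(syn_diffs, nonsyn_diffs)`; both `NA` (with
#'   a warning) when every ordering passes through a stop codon.
#' @examples
#' classify_pair_diffs("TTT", "TTC")  # synonymous single step: c(1, 0)
#' @export
classify_pair_diffs <- function(codon_a, codon_b, genetic_code = "standard") {
  tbl <- codon_table(genetic_code)
  ca <- codon_str_to_index(codon_a)
  cb <- codon_str_to_index(codon_b)
  if (is.na(ca) || is.na(cb))
    stop("ambiguous or invalid codon: ", if (is.na(ca)) codon_a else codon_b)
  if (tbl$is_stop[ca] || tbl$is_stop[cb])
    stop("stop codons cannot be classified")
  s <- tbl$syn_diff[ca, cb]
  if (is.na(s))
    warning(sprintf("no stop-free mutational pathway between %s and %s; pair masked",
                    codon_a, codon_b))
  c(syn_diffs = s, nonsyn_diffs = tbl$nonsyn_diff[ca, cb])
}

# per-sequence NG86 site totals over unmasked codons (matrix of codon indices)
.site_totals <- function(cod, masked, tbl) {
  use <- which(!masked)
  if (!length(use)) stop("alignment has no unmasked codons")
  m <- matrix(tbl$syn_sites[cod[, use, drop = FALSE]], nrow = nrow(cod))
  syn <- rowSums(m)
  list(syn = syn, nonsyn = 3 * length(use) - syn, n_codons = length(use))
}

#' Within-species diversity statistics
#'
#' Computes pairwise nucleotide diversity per site (`pi_total`), synonymous
#' diversity per synonymous site (`pi_S`), non-synonymous diversity per
#' non-synonymous site (`pi_N`), Nei-Gojobori fractional site totals, and
#' segregating-change counts, over the unmasked codons of a within-species
#' alignment.
#'
#' `pi_S` is the mean over all unordered sequence pairs of pathway-classified
#' synonymous differences, divided by the mean per-sequence synonymous site
#' total; `pi_N` analogously. Codon pairs with no stop-free pathway are
#' skipped for that pair with a warning. Segregating counts classify each
#' minor allele codon against the column's major allele.
#'
#' @param alignment a [codon_alignment] with at least 2 sequences.
#' @return an object of class `diversity_stats`: a list with `n_sequences`,
#'   `pi_total`, `pi_S`, `pi_N`, `syn_sites`, `nonsyn_sites`, `n_syn_poly`,
#'   `n_nonsyn_poly`, `n_codons_used`.
#' @export
diversity_stats <- function(alignment) {
  stopifnot(inherits(alignment, "codon_alignment"))
  n <- nrow(alignment$codons)
  if (n < 2L) stop("diversity requires at least 2 sequences")
  tbl <- codon_table(alignment$genetic_code)
  use <- which(!alignment$masked)
  if (!length(use)) stop("alignment has no unmasked codons")
  cod <- alignment$codons[, use, drop = FALSE]

  sites <- .site_totals(alignment$codons, alignment$masked, tbl)
  mean_syn <- mean(sites$syn)
  mean_nonsyn <- mean(sites$nonsyn)

  pairs <- combn(n, 2L)
  n_pairs <- ncol(pairs)
  # all pairs x all codons in one indexing pass
  ij <- cbind(as.vector(cod[pairs[1, ], , drop = FALSE]),
              as.vector(cod[pairs[2, ], , drop = FALSE]))
  s <- tbl$syn_diff[ij]
  blocked <- is.na(s)
  n_blocked <- sum(blocked)
  tot_syn <- sum(s[!blocked])
  tot_non <- sum(tbl$nonsyn_diff[ij][!blocked])
  tot_nt <- sum(tbl$ndiff[ij])  # raw nt differences are defined for all pairs
  if (n_blocked > 0L)
    warning(n_blocked, " codon pair(s) had no stop-free pathway and were skipped")

  # segregating changes: each minor allele vs the column's major allele
  n_syn_poly <- 0
  n_nonsyn_poly <- 0
  variable <- which(colSums(cod != matrix(cod[1, ], n, ncol(cod),
                                          byrow = TRUE)) > 0L)
  for (j in variable) {
    col <- cod[, j]
    tab <- table(col)
    if (length(tab) < 2L) next
    major <- as.integer(names(tab)[which.max(tab)])
    for (alt in as.integer(names(tab))) {
      if (alt == major) next
      sd <- tbl$syn_diff[major, alt]
      if (is.na(sd)) next
      n_syn_poly <- n_syn_poly + sd
      n_nonsyn_poly <- n_nonsyn_poly + tbl$nonsyn_diff[major, alt]
    }
  }

  structure(list(
    n_sequences = n,
    pi_total = (tot_nt / n_pairs) / (3 * length(use)),
    pi_S = (tot_syn / n_pairs) / mean_syn,
    pi_N = (tot_non / n_pairs) / mean_nonsyn,
    syn_sites = mean_syn, nonsyn_sites = mean_nonsyn,
    n_syn_poly = n_syn_poly, n_nonsyn_poly = n_nonsyn_poly,
    n_codons_used = length(use)), class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat(sprintf("diversity_stats: n=%d, pi=%.5g, pi_S=%.5g, pi_N=%.5g (%g syn / %g nonsyn sites)\n",
              x$n_sequences, x$pi_total, x$pi_S, x$pi_N, x$syn_sites,
              x$nonsyn_sites))
  invisible(x)
}

#' Average diversity statistics across species or loci
#'
#' Unweighted arithmetic mean of each statistic, per the averaging rule used
#' for multi-species clades and multi-locus species: one island and one
#' mainland value per comparison per genome.
#'
#' @param stats a list of `diversity_stats` objects (a single object is
#'   returned unchanged).
#' @return a `diversity_stats` object of field-wise means.
#' @export
aggregate_species <- function(stats) {
  if (inherits(stats, "diversity_stats")) return(stats)
  if (!length(stats)) stop("empty input")
  stopifnot(all(vapply(stats, inherits, TRUE, "diversity_stats")))
  if (length(stats) == 1L) return(stats[[1]])
  fields <- c("n_sequences", "pi_total", "pi_S", "pi_N", "syn_sites",
              "nonsyn_sites", "n_syn_poly", "n_nonsyn_poly", "n_codons_used")
  out <- lapply(fields, function(f)
    mean(vapply(stats, function(s) as.numeric(s[[f]]), 0)))
  names(out) <- fields
  structure(out, class = "diversity_stats")
}
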