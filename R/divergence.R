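# divergence: lineage-specific dN, dS and omega for island / mainland /
# outgroup branches by parsimony assignment against the outgroup, NG86
# counting and Jukes-Cantor correction. This is a documented counting-based
# substitute for maximum-likelihood branch models: adequate at low
# divergence, fully specified, and desk-scale.

.BRANCHES <- c("island", "mainland", "outgroup")

#' Majority-rule consensus sequence
#'
#' Per-column majority over the raw characters (including `N`/`-`); ties are
#' broken by the base of the first-listed sequence (logged via `message`).
#'
#' @param alignment a [codon_alignment].
#' @return a single DNA string.
#' @export
representative_sequence <- function(alignment) {
  stopifnot(inherits(alignment, "codon_alignment"))
  if (length(alignment$ids) == 1L) return(alignment$seq[1])
  chars <- do.call(rbind, strsplit(toupper(alignment$seq), "", fixed = TRUE))
  n_ties <- 0L
  cons <- vapply(seq_len(ncol(chars)), function(j) {
    tab <- table(chars[, j])
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) {
      n_ties <<- n_ties + 1L
      if (chars[1, j] %in% top) return(chars[1, j])
      return(top[1])
    }
    top
  }, "")
  if (n_ties > 0L)
    message("representative_sequence: ", n_ties,
            " tied column(s) broken by first-listed sequence")
  paste0(cons, collapse = "")
}

#' Assign codon changes to lineages by parsimony
#'
#' For a three-sequence codon alignment (island, mainland, outgroup), each
#' unmasked variable codon is resolved by parsimony: when two sequences
#' agree, the shared codon is the ancestral state and the changes fall on the
#' disagreeing branch (so a change shared by island and mainland relative to
#' the outgroup is assigned to the outgroup branch); three-way differences
#' are resolved by minimum-change enumeration over all sense-codon ancestral
#' states, with ties split equally among the minimal assignments. Each change
#' is pathway-classified as synonymous or non-synonymous.
#'
#' @param triplet a [codon_alignment] of exactly 3 sequences, ordered island,
#'   mainland, outgroup (or use `roles` to remap).
#' @param roles character vector mapping the 3 sequences to
#'   `c("island","mainland","outgroup")`.
#' @return a list with per-branch `syn_changes` and `nonsyn_changes` (named
#'   numeric vectors over island/mainland/outgroup) and `n_codons_used`.
#' @export
assign_lineage_changes <- function(triplet, roles = .BRANCHES) {
  stopifnot(inherits(triplet, "codon_alignment"))
  if (length(triplet$ids) != 3L)
    stop("parsimony assignment needs exactly 3 sequences (got ",
         length(triplet$ids), ")")
  if (!setequal(roles, .BRANCHES)) stop("roles must be a permutation of island/mainland/outgroup")
  tbl <- codon_table(triplet$genetic_code)
  use <- which(!triplet$masked)
  if (!length(use)) stop("all codons masked")
  ord <- match(.BRANCHES, roles)
  cod <- triplet$codons[ord, use, drop = FALSE]

  syn <- c(island = 0, mainland = 0, outgroup = 0)
  non <- c(island = 0, mainland = 0, outgroup = 0)
  for (j in seq_len(ncol(cod))) {
    ci <- cod[1, j]; cm <- cod[2, j]; co <- cod[3, j]
    if (ci == cm && cm == co) next
    if (ci == cm) {           # change on the outgroup branch
      cls <- c(tbl$syn_diff[ci, co], tbl$nonsyn_diff[ci, co])
      if (anyNA(cls)) { warning("codon ", use[j], ": no stop-free pathway; skipped"); next }
      syn["outgroup"] <- syn["outgroup"] + cls[1]
      non["outgroup"] <- non["outgroup"] + cls[2]
    } else if (ci == co) {    # mainland branch
      cls <- c(tbl$syn_diff[ci, cm], tbl$nonsyn_diff[ci, cm])
      if (anyNA(cls)) { warning("codon ", use[j], ": no stop-free pathway; skipped"); next }
      syn["mainland"] <- syn["mainland"] + cls[1]
      non["mainland"] <- non["mainland"] + cls[2]
    } else if (cm == co) {    # island branch
      cls <- c(tbl$syn_diff[cm, ci], tbl$nonsyn_diff[cm, ci])
      if (anyNA(cls)) { warning("codon ", use[j], ": no stop-free pathway; skipped"); next }
      syn["island"] <- syn["island"] + cls[1]
      non["island"] <- non["island"] + cls[2]
    } else {                  # three-way difference: enumerate ancestors
      leaves <- c(ci, cm, co)
      tot <- tbl$ndiff[tbl$sense, ci] + tbl$ndiff[tbl$sense, cm] +
        tbl$ndiff[tbl$sense, co]
      anc_set <- tbl$sense[tot == min(tot)]
      acc_s <- c(0, 0, 0)
      acc_n <- c(0, 0, 0)
      n_ok <- 0L
      for (a in anc_set) {
        s3 <- tbl$syn_diff[a, leaves]
        n3 <- tbl$nonsyn_diff[a, leaves]
        if (anyNA(s3)) next
        acc_s <- acc_s + s3
        acc_n <- acc_n + n3
        n_ok <- n_ok + 1L
      }
      if (n_ok == 0L) { warning("codon ", use[j], ": no stop-free ancestral assignment; skipped"); next }
      syn <- syn + acc_s / n_ok
      non <- non + acc_n / n_ok
    }
  }
  list(syn_changes = syn, nonsyn_changes = non, n_codons_used = length(use))
}

#' Jukes-Cantor distance from a proportion of differences
#'
#' `d = -(3/4) * log(1 - (4/3) * p)`. Proportions at or above 3/4 are a
#' saturation error; proportions at or above 0.6 trigger a warning (the
#' correction diverges at 3/4).
#'
#' @param p proportion of sites differing (vectorised).
#' @return corrected distance(s).
#' @export
jc_correct <- function(p) {
  if (any(p < 0, na.rm = TRUE)) stop("negative proportion")
  if (any(p >= 0.75, na.rm = TRUE))
    stop("saturation error: proportion of differences >= 3/4, Jukes-Cantor distance undefined")
  if (any(p >= 0.6, na.rm = TRUE))
    warning("proportion of differences >= 0.6: Jukes-Cantor correction unreliable")
  -0.75 * log(1 - (4 / 3) * p)
}

#' Per-branch substitution rates
#'
#' Converts raw change counts into per-site proportions, Jukes-Cantor
#' corrected distances and omega = dN/dS. Omega is `NA` (flagged, not zero)
#' when dS is 0.
#'
#' @param changes output of [assign_lineage_changes()].
#' @param syn_sites,nonsyn_sites NG86 site totals (single numbers applied to
#'   all branches).
#' @return a `lineage_substitution` data.frame with one row per branch:
#'   `branch`, `syn_changes`, `nonsyn_changes`, `syn_sites`, `nonsyn_sites`,
#'   `pS`, `pN`, `dS`, `dN`, `omega`, `omega_defined`.
#' @export
branch_rates <- function(changes, syn_sites, nonsyn_sites) {
  check_nonneg(syn_sites, "syn_sites")
  check_nonneg(nonsyn_sites, "nonsyn_sites")
  if (syn_sites <= 0 || nonsyn_sites <= 0) stop("site counts must be positive")
  pS <- changes$syn_changes / syn_sites
  pN <- changes$nonsyn_changes / nonsyn_sites
  dS <- jc_correct(pS)
  dN <- jc_correct(pN)
  omega <- ifelse(dS > 0, dN / dS, NA_real_)
  data.frame(branch = .BRANCHES,
             syn_changes = unname(changes$syn_changes[.BRANCHES]),
             nonsyn_changes = unname(changes$nonsyn_changes[.BRANCHES]),
             syn_sites = syn_sites, nonsyn_sites = nonsyn_sites,
             pS = unname(pS[.BRANCHES]), pN = unname(pN[.BRANCHES]),
             dS = unname(dS[.BRANCHES]), dN = unname(dN[.BRANCHES]),
             omega = unname(omega[.BRANCHES]),
             omega_defined = unname(dS[.BRANCHES] > 0),
             row.names = NULL)
}

#' Lineage divergence statistics for a three-taxon alignment
#'
#' Convenience wrapper: parsimony assignment plus [branch_rates()], using the
#' mean NG86 site totals of the three sequences as the shared denominators.
#'
#' @inheritParams assign_lineage_changes
#' @return a `lineage_substitution` data.frame (see [branch_rates()]).
#' @export
divergence_stats <- function(triplet, roles = .BRANCHES) {
  tbl <- codon_table(triplet$genetic_code)
  changes <- assign_lineage_changes(triplet, roles)
  sites <- .site_totals(triplet$codons, triplet$masked, tbl)
  branch_rates(changes, mean(sites$syn), mean(sites$nonsyn))
}

# Average-mode divergence for multi-species clades: per focal species a
# triplet against the consensus of the sister clade, then separate averaging
# of dN and dS across species (omega recomputed from the averages).
# island_aln / mainland_aln: one sequence per species of the clade.
.lineage_divergence_average <- function(island_aln, mainland_aln, outgroup_seq,
                                        genome, genetic_code) {
  cons_i <- representative_sequence(island_aln)
  cons_m <- representative_sequence(mainland_aln)
  triplet_of <- function(si, sm) {
    codon_alignment(c(island = si, mainland = sm, outgroup = outgroup_seq),
                    genome = genome, genetic_code = genetic_code)
  }
  row_for <- function(stats, branch) stats[stats$branch == branch, , drop = FALSE]
  isl_rows <- do.call(rbind, lapply(island_aln$seq, function(s)
    row_for(divergence_stats(triplet_of(s, cons_m)), "island")))
  mnl_rows <- do.call(rbind, lapply(mainland_aln$seq, function(s)
    row_for(divergence_stats(triplet_of(cons_i, s)), "mainland")))
  out_row <- row_for(divergence_stats(triplet_of(cons_i, cons_m)), "outgroup")
  avg <- function(rows) {
    num <- vapply(rows[, !(names(rows) %in% c("branch", "omega_defined")),
                       drop = FALSE], mean, 0)
    as.data.frame(as.list(num))
  }
  res <- rbind(cbind(branch = "island", avg(isl_rows)),
               cbind(branch = "mainland", avg(mnl_rows)),
               cbind(branch = "outgroup", avg(out_row)))
  res$omega <- ifelse(res$dS > 0, res$dN / res$dS, NA_real_)
  res$omega_defined <- res$dS > 0
  res
}
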