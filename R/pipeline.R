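# pipeline: orchestration of per-comparison statistics, longest-alignment
# selection, subgroup summaries, correlations and the zero-diversity
# exclusion re-analysis.

#' Analysis configuration
#'
#' @param seed master seed for all stochastic stages (bootstrap).
#' @param n_boot bootstrap replicates (default 1000).
#' @param beta gamma-DFE shape parameter used for omega-to-Ne conversions.
#' @param wilcoxon_exact_max largest number of nonzero differences for which
#'   the exact signed-rank null is enumerated.
#' @param divergence_mode `"average"` (per-species triplets against the
#'   sister-clade consensus, then separate averaging of dN and dS) or
#'   `"consensus"` (a single consensus-vs-consensus triplet).
#' @param genome_precedence tie-break order for the longest-alignment rule.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(seed = 1L, n_boot = 1000L, beta = 0.5,
                            wilcoxon_exact_max = 20L,
                            divergence_mode = c("average", "consensus"),
                            genome_precedence = c("mitochondrial", "nuclear",
                                                  "chloroplast")) {
  divergence_mode <- match.arg(divergence_mode)
  stopifnot(setequal(genome_precedence, GENOME_TYPES))
  structure(list(seed = as.integer(seed), n_boot = as.integer(n_boot),
                 beta = beta, wilcoxon_exact_max = as.integer(wilcoxon_exact_max),
                 divergence_mode = divergence_mode,
                 genome_precedence = genome_precedence),
            class = "analysis_config")
}

#' Read an analysis configuration from a plain-text key=value file
#'
#' Recognised keys: `seed`, `n_boot`, `beta`, `wilcoxon_exact_max`,
#' `divergence_mode`, `genome_precedence` (comma-separated). Blank lines and
#' `#` comments are ignored; unknown keys raise an error so typos do not
#' silently fall back to defaults.
#'
#' @param path config file.
#' @return an [analysis_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!all(grepl("=", lines, fixed = TRUE)))
    stop("config lines must be key=value")
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  known <- c("seed", "n_boot", "beta", "wilcoxon_exact_max",
             "divergence_mode", "genome_precedence")
  bad <- setdiff(keys, known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  args <- list()
  for (i in seq_along(keys)) {
    args[[keys[i]]] <- switch(keys[i],
      seed = , n_boot = , wilcoxon_exact_max = as.integer(vals[i]),
      beta = as.numeric(vals[i]),
      divergence_mode = vals[i],
      genome_precedence = trimws(strsplit(vals[i], ",")[[1]]))
  }
  do.call(analysis_config, args)
}

# subset a codon alignment to the given ids (kept in the given order)
subset_alignment <- function(aln, ids) {
  idx <- match(ids, aln$ids)
  if (anyNA(idx)) stop("ids not in alignment: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  codon_alignment(aln$seq[idx], ids = aln$ids[idx], genome = aln$genome,
                  genetic_code = aln$genetic_code)
}

#' Run all statistics for one comparison
#'
#' Reads the polymorphism alignments (per species, possibly several loci),
#' computes per-species diversity aggregated island-side and mainland-side,
#' computes lineage divergence from the three-taxon (or pruned multi-taxon)
#' alignment, and derives the selection summaries. Stage errors are recorded
#' on the result, never silently dropped.
#'
#' @param entry one manifest entry (see [read_manifest()]).
#' @param base_dir directory that file paths in the manifest are relative to.
#' @param config an [analysis_config()].
#' @return a `comparison_result` list.
#' @export
run_comparison <- function(entry, base_dir = ".", config = analysis_config()) {
  stopifnot(inherits(entry, "comparison_entry"))
  res <- list(comparison_id = entry$comparison_id, group_id = entry$group_id,
              genome = entry$genome, taxon_group = entry$taxon_group,
              direction = entry$direction,
              range_ratio = if (!is.na(entry$island_range_km2) &&
                                !is.na(entry$mainland_range_km2) &&
                                entry$mainland_range_km2 > 0)
                entry$island_range_km2 / entry$mainland_range_km2 else NA_real_,
              island_div = NULL, mainland_div = NULL, lineage = NULL,
              alignment_length = NA_integer_, notes = character())

  species_div <- function(sp) {
    paths <- entry$polymorphism_files[[sp]]
    if (is.null(paths)) return(NULL)
    loci <- lapply(paths, function(p)
      diversity_stats(read_codon_alignment(file.path(base_dir, p),
                                           genetic_code = entry$genetic_code,
                                           genome = entry$genome)))
    aggregate_species(loci)
  }

  poly_len <- 0L
  if (length(entry$polymorphism_files)) {
    isl <- Filter(Negate(is.null),
                  lapply(entry$island_species, species_div))
    mnl <- Filter(Negate(is.null),
                  lapply(entry$mainland_species, species_div))
    if (length(isl)) res$island_div <- aggregate_species(isl)
    if (length(mnl)) res$mainland_div <- aggregate_species(mnl)
    lens <- vapply(unlist(entry$polymorphism_files), function(p) {
      3L * diversity_stats_length(file.path(base_dir, p))
    }, 0L)
    poly_len <- max(lens)
  }

  div_len <- 0L
  if (!is.na(entry$divergence_file)) {
    aln <- read_codon_alignment(file.path(base_dir, entry$divergence_file),
                                genetic_code = entry$genetic_code,
                                genome = entry$genome)
    validate_divergence_alignment(aln, entry)
    div_len <- aln$length_nt
    isl_aln <- subset_alignment(aln, entry$island_species)
    mnl_aln <- subset_alignment(aln, entry$mainland_species)
    out_seq <- aln$seq[match(entry$outgroup_species, aln$ids)]
    if (config$divergence_mode == "average") {
      res$lineage <- .lineage_divergence_average(isl_aln, mnl_aln, out_seq,
                                                 entry$genome,
                                                 entry$genetic_code)
    } else {
      tri <- codon_alignment(c(representative_sequence(isl_aln),
                               representative_sequence(mnl_aln), out_seq),
                             ids = c("island", "mainland", "outgroup"),
                             genome = entry$genome,
                             genetic_code = entry$genetic_code)
      res$lineage <- divergence_stats(tri)
    }
  }
  res$alignment_length <- max(poly_len, div_len)

  g <- function(x, f) if (is.null(x)) NA_real_ else as.numeric(x[[f]])
  b <- function(br, f) {
    if (is.null(res$lineage)) return(NA_real_)
    res$lineage[res$lineage$branch == br, f]
  }
  res$island_selection <- selection_summary(g(res$island_div, "pi_N"),
                                            g(res$island_div, "pi_S"),
                                            b("island", "dN"),
                                            b("island", "dS"))
  res$mainland_selection <- selection_summary(g(res$mainland_div, "pi_N"),
                                              g(res$mainland_div, "pi_S"),
                                              b("mainland", "dN"),
                                              b("mainland", "dS"))
  class(res) <- "comparison_result"
  res
}

# number of codons in a FASTA alignment without full validation overhead
diversity_stats_length <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  as.integer(Biostrings::width(ss)[1] %/% 3L)
}

# flatten one comparison_result (or an error placeholder) to a data.frame row
.result_row <- function(res) {
  if (!is.null(res$error)) {
    return(data.frame(comparison_id = res$comparison_id,
                      group_id = res$group_id, genome = NA_character_,
                      taxon_group = NA_character_, direction = NA_character_,
                      range_ratio = NA_real_, alignment_length = NA_integer_,
                      pi_S_island = NA_real_, pi_S_mainland = NA_real_,
                      pi_N_island = NA_real_, pi_N_mainland = NA_real_,
                      pnf_island = NA_real_, pnf_mainland = NA_real_,
                      dS_island = NA_real_, dS_mainland = NA_real_,
                      dS_outgroup = NA_real_,
                      dN_island = NA_real_, dN_mainland = NA_real_,
                      omega_island = NA_real_, omega_mainland = NA_real_,
                      dos_island = NA_real_, dos_mainland = NA_real_,
                      ne_island = NA_real_, ne_mainland = NA_real_,
                      error = res$error, stringsAsFactors = FALSE))
  }
  g <- function(x, f) if (is.null(x)) NA_real_ else as.numeric(x[[f]])
  b <- function(br, f) {
    if (is.null(res$lineage)) return(NA_real_)
    as.numeric(res$lineage[res$lineage$branch == br, f])
  }
  data.frame(comparison_id = res$comparison_id, group_id = res$group_id,
             genome = res$genome, taxon_group = res$taxon_group,
             direction = res$direction, range_ratio = res$range_ratio,
             alignment_length = res$alignment_length,
             pi_S_island = g(res$island_div, "pi_S"),
             pi_S_mainland = g(res$mainland_div, "pi_S"),
             pi_N_island = g(res$island_div, "pi_N"),
             pi_N_mainland = g(res$mainland_div, "pi_N"),
             pnf_island = res$island_selection$pn_fraction,
             pnf_mainland = res$mainland_selection$pn_fraction,
             dS_island = b("island", "dS"), dS_mainland = b("mainland", "dS"),
             dS_outgroup = b("outgroup", "dS"),
             dN_island = b("island", "dN"), dN_mainland = b("mainland", "dN"),
             omega_island = b("island", "omega"),
             omega_mainland = b("mainland", "omega"),
             dos_island = res$island_selection$dos,
             dos_mainland = res$mainland_selection$dos,
             ne_island = res$island_selection$ne_proxy,
             ne_mainland = res$mainland_selection$ne_proxy,
             error = NA_character_, stringsAsFactors = FALSE)
}

# longest-alignment selection within group_id, genome-precedence tie-break
.select_longest <- function(df, precedence) {
  keep <- unlist(lapply(split(seq_len(nrow(df)), df$group_id), function(idx) {
    if (length(idx) == 1L) return(idx)
    lens <- df$alignment_length[idx]
    cand <- idx[which(lens == max(lens, na.rm = TRUE))]
    if (length(cand) > 1L) {
      ord <- match(df$genome[cand], precedence)
      cand <- cand[order(ord)][1]
      message("longest-alignment tie in group '", df$group_id[cand],
              "' broken by genome precedence")
    }
    cand
  }))
  sort(unname(keep))
}

# one summary row for a relative-value statistic on a subset
.sum_row <- function(df, rows, col_i, col_m, label, tail, config, seed_offset,
                     spearman_vs = NULL) {
  sub <- df[rows, , drop = FALSE]
  ps <- paired_summary(sub[[col_i]], sub[[col_m]], statistic_name = label,
                       tail = tail, n_boot = config$n_boot,
                       seed = config$seed + seed_offset,
                       exact_max = config$wilcoxon_exact_max)
  ps$dataset <- label
  if (!is.null(spearman_vs)) {
    rel <- relative_value(sub[[col_i]], sub[[col_m]])
    ok <- !is.na(rel) & !is.na(sub[[spearman_vs]])
    ps$spearman_rho <- if (sum(ok) >= 3 &&
                           length(unique(rel[ok])) > 1 &&
                           length(unique(sub[[spearman_vs]][ok])) > 1)
      correlate(sub[[spearman_vs]][ok], rel[ok], "spearman")$coefficient
    else NA_real_
  }
  ps
}

# standard subgroup splits: combined, per genome, per taxon
.subgroup_rows <- function(df) {
  rows <- list(Combined = seq_len(nrow(df)))
  for (gn in intersect(c("mitochondrial", "nuclear", "chloroplast"),
                       unique(df$genome)))
    rows[[gn]] <- which(df$genome == gn)
  for (tx in intersect(TAXON_GROUPS, unique(df$taxon_group)))
    rows[[tx]] <- which(df$taxon_group == tx)
  rows
}

.summary_table <- function(df, col_i, col_m, tail, config, seed_offset,
                           splits = .subgroup_rows(df), spearman_vs = NULL) {
  out <- do.call(rbind, lapply(seq_along(splits), function(k)
    .sum_row(df, splits[[k]], col_i, col_m, names(splits)[k], tail, config,
             seed_offset + k, spearman_vs = spearman_vs)))
  rownames(out) <- NULL
  out
}

#' Effective-population-size comparison
#'
#' Relative island values of the pi_S/d_S proxy, Wilcoxon signed-rank test
#' and bootstrap CI of the mean relative value, also expressed as an
#' island/mainland percentage `100 * r / (1 - r)` (the same monotone
#' transform is applied to the CI endpoints).
#'
#' @param per_comparison the per-comparison data.frame of [run_dataset()].
#' @param config an [analysis_config()].
#' @return a one-row data.frame with the paired summary plus
#'   `pct_island_over_mainland`, `pct_lower`, `pct_upper`.
#' @export
ne_comparison <- function(per_comparison, config = analysis_config()) {
  ps <- .sum_row(per_comparison, seq_len(nrow(per_comparison)),
                 "ne_island", "ne_mainland", "Ne proxy (pi_S/d_S)",
                 tail = "two_sided", config = config, seed_offset = 900L)
  pct <- function(r) ifelse(is.na(r) | r >= 1, NA_real_, 100 * r / (1 - r))
  ps$pct_island_over_mainland <- pct(ps$mean_relative_island)
  ps$pct_lower <- pct(ps$ci_lower)
  ps$pct_upper <- pct(ps$ci_upper)
  ps
}

#' Run the full paired island-mainland analysis
#'
#' Executes every comparison in the manifest (stage errors are recorded per
#' comparison and the run continues), applies the longest-alignment genome
#' selection within `group_id`, and emits the summary tables of the paired
#' analysis: synonymous diversity (one-tailed, island lower), pi_N/(pi_N+pi_S)
#' (one-tailed, island greater), omega and d_S (two-tailed, with
#' colonization-direction splits for omega), DoS (paired differences), the Ne
#' proxy comparison, scatter/histogram data for relative pi_S vs divergence
#' and pi_S:d_S, and the zero-diversity exclusion re-analysis.
#'
#' @param manifest a `comparison_manifest` or path to a manifest TSV.
#' @param base_dir directory for relative paths (defaults to the manifest's
#'   directory when `manifest` is a path, else `"."`).
#' @param config an [analysis_config()].
#' @return a list with `per_comparison` (all rows), `selected` (after the
#'   longest-alignment rule), `tables` (named list: `pi_s`, `pn_fraction`,
#'   `omega`, `d_s`, `dos`, `ne`, `pi_s_excluding_zero`), `fig2`, `fig2_cor`,
#'   `fig3`, `provenance`.
#' @export
run_dataset <- function(manifest, base_dir = NULL,
                        config = analysis_config()) {
  if (is.character(manifest)) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  if (is.null(base_dir)) base_dir <- "."
  stopifnot(inherits(manifest, "comparison_manifest"))

  results <- lapply(manifest, function(entry) {
    tryCatch(run_comparison(entry, base_dir, config),
             error = function(e) list(comparison_id = entry$comparison_id,
                                      group_id = entry$group_id,
                                      error = conditionMessage(e)))
  })
  per_comparison <- do.call(rbind, lapply(results, .result_row))
  ok <- is.na(per_comparison$error)
  if (!all(ok))
    warning(sum(!ok), " comparison(s) failed; see per_comparison$error")

  sel_idx <- .select_longest(per_comparison[ok, , drop = FALSE],
                             config$genome_precedence)
  df <- per_comparison[ok, , drop = FALSE][sel_idx, , drop = FALSE]

  tables <- list()
  tables$pi_s <- .summary_table(df, "pi_S_island", "pi_S_mainland",
                                tail = "less", config = config,
                                seed_offset = 100L,
                                spearman_vs = "range_ratio")
  tables$pn_fraction <- .summary_table(df, "pnf_island", "pnf_mainland",
                                       tail = "greater", config = config,
                                       seed_offset = 200L)
  omega_splits <- .subgroup_rows(df)
  omega_splits[["I->M"]] <- which(df$direction == "island_to_mainland")
  omega_splits[["M->I"]] <- which(df$direction == "mainland_to_island")
  for (gn in intersect(c("mitochondrial", "nuclear", "chloroplast"),
                       unique(df$genome)))
    omega_splits[[paste0("M->I ", gn)]] <-
      which(df$direction == "mainland_to_island" & df$genome == gn)
  for (tx in intersect(TAXON_GROUPS, unique(df$taxon_group)))
    omega_splits[[paste0("M->I ", tx)]] <-
      which(df$direction == "mainland_to_island" & df$taxon_group == tx)
  tables$omega <- .summary_table(df, "omega_island", "omega_mainland",
                                 tail = "two_sided", config = config,
                                 seed_offset = 300L, splits = omega_splits)
  tables$d_s <- .summary_table(df, "dS_island", "dS_mainland",
                               tail = "two_sided", config = config,
                               seed_offset = 400L)

  dos_splits <- list(Combined = seq_len(nrow(df)),
                     `I->M` = which(df$direction == "island_to_mainland"),
                     `M->I` = which(df$direction == "mainland_to_island"))
  tables$dos <- do.call(rbind, lapply(seq_along(dos_splits), function(k) {
    sub <- df[dos_splits[[k]], , drop = FALSE]
    d <- sub$dos_island - sub$dos_mainland
    defined <- !is.na(d)
    p <- if (sum(defined) && any(d[defined] != 0))
      wilcoxon_signed_rank(d[defined], 0, "two_sided",
                           exact_max = config$wilcoxon_exact_max)$p_value
    else if (sum(defined)) 1 else NA_real_
    data.frame(dataset = names(dos_splits)[k], n_comparisons = sum(defined),
               n_excluded = sum(!defined),
               mean_island_dos = if (sum(defined)) mean(sub$dos_island[defined]) else NA_real_,
               mean_mainland_dos = if (sum(defined)) mean(sub$dos_mainland[defined]) else NA_real_,
               wilcoxon_p = p, stringsAsFactors = FALSE)
  }))

  tables$ne <- ne_comparison(df, config)

  # zero-diversity exclusion re-analysis (comparisons with island pi_S = 0
  # dropped, combined row recomputed)
  nz <- which(!is.na(df$pi_S_island) & df$pi_S_island > 0)
  tables$pi_s_excluding_zero <- .sum_row(df, nz, "pi_S_island",
                                         "pi_S_mainland",
                                         "Combined, island pi_S > 0",
                                         tail = "less", config = config,
                                         seed_offset = 500L)

  # figure data: relative pi_S against island+mainland branch d_S
  fig2 <- data.frame(comparison_id = df$comparison_id,
                     relative_pi_S = relative_value(df$pi_S_island,
                                                    df$pi_S_mainland),
                     d_S_total = df$dS_island + df$dS_mainland,
                     direction = df$direction, stringsAsFactors = FALSE)
  cc <- !is.na(fig2$relative_pi_S) & !is.na(fig2$d_S_total)
  fig2_cor <- if (sum(cc) >= 3 && length(unique(fig2$relative_pi_S[cc])) > 1 &&
                  length(unique(fig2$d_S_total[cc])) > 1) {
    ct <- correlate(fig2$d_S_total[cc], fig2$relative_pi_S[cc], "pearson")
    data.frame(r = ct$coefficient, p_value = ct$p_value, n = ct$n)
  } else data.frame(r = NA_real_, p_value = NA_real_, n = sum(cc))
  fig3 <- data.frame(comparison_id = df$comparison_id,
                     pi_s_over_d_s = ifelse(df$dS_island + df$dS_mainland > 0,
                                            df$pi_S_island /
                                              (df$dS_island + df$dS_mainland),
                                            NA_real_),
                     stringsAsFactors = FALSE)

  provenance <- list(package = "islemol",
                     version = as.character(utils::packageVersion("islemol")),
                     config = unclass(config),
                     n_manifest = length(manifest),
                     n_ok = sum(ok), n_selected = nrow(df),
                     divergence_estimator = "outgroup parsimony + NG86 counting + Jukes-Cantor (counting-based substitute for ML branch models)")

  list(per_comparison = per_comparison, selected = df, tables = tables,
       fig2 = fig2, fig2_cor = fig2_cor, fig3 = fig3,
       provenance = provenance)
}

#' Write analysis results to TSV files
#'
#' One TSV per summary table plus the per-comparison table and figure data;
#' every file starts with commented provenance lines (config, seed, package
#' version) so stochastic stages are reproducible.
#'
#' @param results output of [run_dataset()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prov <- results$provenance
  header <- c(sprintf("# %s %s", prov$package, prov$version),
              sprintf("# seed: %d; n_boot: %d; beta: %g; divergence_mode: %s",
                      prov$config$seed, prov$config$n_boot, prov$config$beta,
                      prov$config$divergence_mode),
              sprintf("# divergence estimator: %s", prov$divergence_estimator))
  emit <- function(x, name) {
    path <- file.path(dir, paste0(name, ".tsv"))
    con <- file(path, "w")
    writeLines(header, con)
    write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  for (nm in names(results$tables)) emit(results$tables[[nm]], nm)
  emit(results$per_comparison, "per_comparison")
  emit(results$fig2, "fig2_data")
  emit(results$fig2_cor, "fig2_correlation")
  emit(results$fig3, "fig3_data")
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
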