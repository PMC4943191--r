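# synthetic_data: coalescent island-colonization sequence generator.
#
# Haploid (organellar-style) structured coalescent with a mainland-to-island
# split, an optional founder bottleneck at the split, and a deep outgroup;
# finite-sites Poisson mutation on explicit codon backgrounds so downstream
# codon machinery is exercised on realistic multi-hit codons. Purifying
# selection is emulated by mutation rejection: synonymous mutations are
# always accepted, stop-creating mutations never, and non-synonymous
# mutations are neutral with probability `nonsyn_neutral_fraction`, slightly
# deleterious with probability `nonsyn_weak_fraction` (accepted only on
# genealogy edges that segregate within one deme's sample, so they
# contribute to polymorphism but not divergence), and effectively lethal
# otherwise.

#' Scenario parameters for the island-colonization generator
#'
#' Defaults describe a mitochondrial-like island-mainland comparison: 250
#' codons (750 nt), theta = 0.03 per nucleotide site, 7 samples per species,
#' a mainland-to-island split 20 x 2N generations ago with no bottleneck, an
#' outgroup twice as deep, and purifying selection leaving 20% of
#' non-synonymous mutations neutral and 10% slightly deleterious.
#'
#' @param n_codons number of codons per sequence.
#' @param theta population-scaled mutation rate per nucleotide site (2N mu
#'   for a haploid locus).
#' @param split_time island-mainland split, in units of 2N generations.
#' @param bottleneck_founders number of founding lineages at colonization
#'   (`NULL` for no bottleneck).
#' @param sample_sizes named vector `c(island =, mainland =)`, each >= 2.
#' @param outgroup_time outgroup divergence, in units of 2N generations.
#' @param nonsyn_neutral_fraction fraction of non-synonymous mutations that
#'   are neutral (accepted everywhere).
#' @param nonsyn_weak_fraction fraction of non-synonymous mutations that are
#'   slightly deleterious: accepted only on edges segregating within one
#'   deme's sample (polymorphism, not divergence). The two fractions must sum
#'   to at most 1; the remainder is rejected outright.
#' @param migration_rate scaled symmetric migration rate between demes before
#'   the split (default 0, mitochondrial-like isolation).
#' @param genome genome tag for generated alignments.
#' @param genetic_code genetic code (default: NCBI convention for `genome`).
#' @param seed integer seed (`NULL` uses the current RNG stream).
#' @return a validated `scenario_params` list.
#' @export
scenario_params <- function(n_codons = 250L, theta = 0.03, split_time = 20,
                            bottleneck_founders = NULL,
                            sample_sizes = c(island = 7L, mainland = 7L),
                            outgroup_time = 40,
                            nonsyn_neutral_fraction = 0.2,
                            nonsyn_weak_fraction = 0.1,
                            migration_rate = 0,
                            genome = "mitochondrial", genetic_code = NULL,
                            seed = NULL) {
  stopifnot(n_codons >= 1L)
  check_nonneg(theta, "theta")
  check_nonneg(split_time, "split_time")
  check_nonneg(outgroup_time, "outgroup_time")
  check_nonneg(migration_rate, "migration_rate")
  if (outgroup_time < split_time)
    stop("outgroup_time must be at least split_time")
  if (!is.null(bottleneck_founders)) {
    stopifnot(is.numeric(bottleneck_founders), bottleneck_founders >= 1)
    bottleneck_founders <- as.integer(bottleneck_founders)
  }
  if (is.null(names(sample_sizes)))
    names(sample_sizes) <- c("island", "mainland")
  if (any(sample_sizes < 2L))
    stop("sample sizes must be at least 2")
  check_nonneg(nonsyn_neutral_fraction, "nonsyn_neutral_fraction")
  check_nonneg(nonsyn_weak_fraction, "nonsyn_weak_fraction")
  if (nonsyn_neutral_fraction > 1 || nonsyn_weak_fraction > 1 ||
      nonsyn_neutral_fraction + nonsyn_weak_fraction > 1)
    stop("non-synonymous fractions must lie in [0,1] and sum to at most 1")
  genome <- check_enum(genome, GENOME_TYPES, "genome")
  if (is.null(genetic_code)) genetic_code <- default_genetic_code(genome)
  genetic_code <- check_enum(genetic_code, GENETIC_CODES, "genetic_code")
  structure(list(n_codons = as.integer(n_codons), theta = theta,
                 split_time = split_time,
                 bottleneck_founders = bottleneck_founders,
                 sample_sizes = c(island = as.integer(sample_sizes[["island"]]),
                                  mainland = as.integer(sample_sizes[["mainland"]])),
                 outgroup_time = outgroup_time,
                 nonsyn_neutral_fraction = nonsyn_neutral_fraction,
                 nonsyn_weak_fraction = nonsyn_weak_fraction,
                 migration_rate = migration_rate,
                 genome = genome, genetic_code = genetic_code, seed = seed),
            class = "scenario_params")
}

# Structured coalescent genealogy. Returns node vectors (time, parent) with
# tips 1..(n_i + n_m [+1 outgroup]); parents always have larger ids than
# their children. Island tips come first, then mainland, then the outgroup.
.sim_genealogy <- function(n_i, n_m, split_time, founders, migration,
                           outgroup_time, include_outgroup) {
  n_tips <- n_i + n_m + as.integer(include_outgroup)
  time <- numeric(n_tips)
  parent <- rep(NA_integer_, n_tips)
  new_node <- function(t) {
    time[length(time) + 1L] <<- t
    parent[length(parent) + 1L] <<- NA_integer_
    length(time)
  }
  merge_pair <- function(a, b, t) {
    p <- new_node(t)
    parent[a] <<- p
    parent[b] <<- p
    p
  }
  act_i <- seq_len(n_i)
  act_m <- n_i + seq_len(n_m)
  og <- if (include_outgroup) n_i + n_m + 1L else NA_integer_

  t <- 0
  repeat {  # phase 1: two demes until the split
    ki <- length(act_i)
    km <- length(act_m)
    rate_ci <- ki * (ki - 1) / 2
    rate_cm <- km * (km - 1) / 2
    rate_mig <- (ki + km) * migration / 2
    total <- rate_ci + rate_cm + rate_mig
    if (total == 0) { t <- split_time; break }
    dt <- rexp(1, total)
    if (t + dt >= split_time) { t <- split_time; break }
    t <- t + dt
    u <- runif(1) * total
    if (u < rate_ci) {
      pick <- sample(act_i, 2L)
      p <- merge_pair(pick[1], pick[2], t)
      act_i <- c(setdiff(act_i, pick), p)
    } else if (u < rate_ci + rate_cm) {
      pick <- sample(act_m, 2L)
      p <- merge_pair(pick[1], pick[2], t)
      act_m <- c(setdiff(act_m, pick), p)
    } else {
      if (runif(1) < ki / (ki + km) && ki > 0) {
        mv <- if (ki == 1L) act_i else sample(act_i, 1L)
        act_i <- setdiff(act_i, mv)
        act_m <- c(act_m, mv)
      } else if (km > 0) {
        mv <- if (km == 1L) act_m else sample(act_m, 1L)
        act_m <- setdiff(act_m, mv)
        act_i <- c(act_i, mv)
      }
    }
  }

  # founder bottleneck: island lineages pick one of `founders` founding
  # lineages; same-founder groups coalesce instantly at the split
  if (!is.null(founders) && length(act_i) > 1L) {
    grp <- sample.int(founders, length(act_i), replace = TRUE)
    survivors <- integer(0)
    for (g in unique(grp)) {
      members <- act_i[grp == g]
      while (length(members) > 1L) {
        p <- merge_pair(members[1], members[2], split_time)
        members <- c(members[-(1:2)], p)
      }
      survivors <- c(survivors, members)
    }
    act_i <- survivors
  }

  act <- c(act_m, act_i)  # merged ancestral (mainland) population
  while (length(act) > 1L) {
    k <- length(act)
    t <- t + rexp(1, k * (k - 1) / 2)
    pick <- sample(act, 2L)
    p <- merge_pair(pick[1], pick[2], t)
    act <- c(setdiff(act, pick), p)
  }
  t_mrca <- time[act]

  root <- act
  if (include_outgroup) {
    t_root <- max(outgroup_time, t_mrca) + rexp(1, 1)
    root <- merge_pair(act, og, t_root)
  }
  list(time = time, parent = parent, n_island = n_i, n_mainland = n_m,
       outgroup_tip = og, root = root, t_mrca_ingroup = t_mrca)
}

# per-node flag: does the edge above this node segregate strictly within one
# deme's sample? (mutations on such edges are polymorphism, never divergence)
.segregating_edges <- function(gen) {
  n_nodes <- length(gen$time)
  di <- integer(n_nodes)
  dm <- integer(n_nodes)
  di[seq_len(gen$n_island)] <- 1L
  dm[gen$n_island + seq_len(gen$n_mainland)] <- 1L
  for (v in seq_len(n_nodes)) {  # children always precede parents
    p <- gen$parent[v]
    if (!is.na(p)) {
      di[p] <- di[p] + di[v]
      dm[p] <- dm[p] + dm[v]
    }
  }
  (di > 0L & di < gen$n_island & dm == 0L) |
    (dm > 0L & dm < gen$n_mainland & di == 0L)
}

# Evolve a sequence along one edge. Mutations at distinct codons commute;
# within-codon multiples are applied in random order, one "round" at a time.
.mutate_edge <- function(seq, len, tbl, theta, f_neutral, f_weak, segregating) {
  if (len <= 0) return(seq)
  n_sites <- 3L * length(seq)
  n_mut <- rpois(1L, len * theta / 2 * n_sites)
  if (n_mut == 0L) return(seq)
  site <- sample.int(n_sites, n_mut, replace = TRUE)
  alt <- sample.int(3L, n_mut, replace = TRUE)
  u <- runif(n_mut)
  cod <- (site - 1L) %/% 3L + 1L
  pos <- (site - 1L) %% 3L + 1L
  remaining <- if (n_mut > 1L) sample.int(n_mut) else 1L
  while (length(remaining)) {
    first <- remaining[!duplicated(cod[remaining])]
    remaining <- setdiff(remaining, first)
    cur <- seq[cod[first]]
    nxt <- tbl$mut_idx[cbind(cur, pos[first], alt[first])]
    syn <- tbl$aa[nxt] == tbl$aa[cur]
    ok <- !tbl$is_stop[nxt] &
      (syn | u[first] < f_neutral |
         (segregating & u[first] >= f_neutral & u[first] < f_neutral + f_weak))
    seq[cod[first][ok]] <- nxt[ok]
  }
  seq
}

# Analytic expected pi_S / pi_N (per NG86 site) for a given root sequence.
# Two finite-rate effects of the stated mutation model are included:
#   - stop-mutant rejection shrinks the realized synonymous rate below theta
#     (linear factor sum(s_mut/3)/syn_sites);
#   - back/parallel mutation at a site saturates observed differences. Under
#     a Jukes-Cantor site with rate r per lineage, two tips separated by
#     2*T2 differ with probability (3/4)(1 - exp(-(8/3) r T2)); integrating
#     over T2 ~ Exp(1) gives 2r / (1 + (8/3) r), i.e. the linear value times
#     1 / (1 + 4*theta/3) at r = theta/2.
.expected_pi <- function(root_seq, tbl, theta, f_neutral, f_weak) {
  s_mut <- tbl$n_syn_mut[root_seq]          # synonymous single-mutants (of 9)
  x_mut <- tbl$n_stop_mut[root_seq]         # stop single-mutants
  n_mut <- 9L - s_mut - x_mut               # non-syn, non-stop
  syn_sites <- sum(tbl$syn_sites[root_seq])
  nonsyn_sites <- sum(tbl$nonsyn_sites[root_seq])
  f <- f_neutral + f_weak
  list(pi_S = theta * sum(s_mut / 3) / syn_sites / (1 + 4 * theta / 3),
       pi_N = theta * f * sum(n_mut / 3) / nonsyn_sites /
         (1 + 4 * f * theta / 3))
}

#' Simulate one island-mainland comparison
#'
#' Simulates a structured coalescent genealogy (island and mainland demes,
#' mainland-to-island split with optional founder bottleneck, deep outgroup),
#' places Poisson mutations on branches at rate theta/2 per nucleotide site,
#' filters them through the selection scheme, and returns within-species
#' alignments for both demes plus a three-taxon divergence alignment and a
#' truth record.
#'
#' @param params a [scenario_params] object.
#' @param polymorphism_only if `TRUE`, skip the outgroup and divergence
#'   alignment and evolve sequences only below the ingroup ancestor (the
#'   portion above it is shared by all samples and affects no within- or
#'   between-deme statistic); substantially faster for diversity-only
#'   calibration runs.
#' @param id_prefix prefix for sequence/species identifiers.
#' @return list with elements `island`, `mainland` ([codon_alignment]s of the
#'   sampled sequences), `triplet` (3-taxon [codon_alignment] of island
#'   representative, mainland representative, outgroup; `NULL` when
#'   `polymorphism_only`), and `truth` (realized genealogy statistics and
#'   analytic expectations).
#' @export
simulate_comparison <- function(params, polymorphism_only = FALSE,
                                id_prefix = "sim") {
  stopifnot(inherits(params, "scenario_params"))
  with_seed(params$seed, {
    tbl <- codon_table(params$genetic_code)
    gen <- .sim_genealogy(params$sample_sizes[["island"]],
                          params$sample_sizes[["mainland"]],
                          params$split_time, params$bottleneck_founders,
                          params$migration_rate, params$outgroup_time,
                          include_outgroup = !polymorphism_only)
    seg <- .segregating_edges(gen)
    root_seq <- sample(tbl$sense, params$n_codons, replace = TRUE)

    n_nodes <- length(gen$time)
    seqs <- vector("list", n_nodes)
    seqs[[gen$root]] <- root_seq
    for (v in seq.int(n_nodes, 1L)) {
      if (v == gen$root) next
      p <- gen$parent[v]
      if (is.na(p)) next  # disconnected only when polymorphism_only trims nothing
      seqs[[v]] <- .mutate_edge(seqs[[p]], gen$time[p] - gen$time[v], tbl,
                                params$theta, params$nonsyn_neutral_fraction,
                                params$nonsyn_weak_fraction, seg[v])
    }

    n_i <- gen$n_island
    n_m <- gen$n_mainland
    isl_seqs <- vapply(seq_len(n_i), function(i) codons_to_dna(seqs[[i]]), "")
    mnl_seqs <- vapply(seq_len(n_m),
                       function(i) codons_to_dna(seqs[[n_i + i]]), "")
    island <- codon_alignment(isl_seqs,
                              ids = sprintf("%s_isl_%d", id_prefix, seq_len(n_i)),
                              genome = params$genome,
                              genetic_code = params$genetic_code)
    mainland <- codon_alignment(mnl_seqs,
                                ids = sprintf("%s_main_%d", id_prefix, seq_len(n_m)),
                                genome = params$genome,
                                genetic_code = params$genetic_code)
    triplet <- NULL
    if (!polymorphism_only) {
      triplet <- codon_alignment(
        c(codons_to_dna(seqs[[1]]), codons_to_dna(seqs[[n_i + 1]]),
          codons_to_dna(seqs[[gen$outgroup_tip]])),
        ids = sprintf("%s_%s", id_prefix, c("isl", "main", "out")),
        genome = params$genome, genetic_code = params$genetic_code)
    }
    exp_pi <- .expected_pi(root_seq, tbl, params$theta,
                           params$nonsyn_neutral_fraction,
                           params$nonsyn_weak_fraction)
    truth <- list(params = unclass(params)[setdiff(names(params), "seed")],
                  seed = params$seed,
                  t_mrca_ingroup = gen$t_mrca_ingroup,
                  t_root = if (polymorphism_only) NA_real_ else gen$time[gen$root],
                  expected_pi_S = exp_pi$pi_S,
                  expected_pi_N = exp_pi$pi_N)
    list(island = island, mainland = mainland, triplet = triplet,
         truth = truth)
  })
}

#' Simulate a full dataset on disk
#'
#' Writes per-comparison FASTA files (within-species island and mainland
#' alignments plus a three-taxon divergence alignment), a manifest TSV
#' consumable by [run_dataset()] unchanged, and a JSON truth sidecar per
#' comparison. Fully deterministic given `seed`.
#'
#' @param n_comparisons number of comparisons.
#' @param params a single [scenario_params] (recycled) or a list of length
#'   `n_comparisons`.
#' @param dir output directory (created if needed).
#' @param seed master seed; per-comparison seeds are derived from it (any
#'   `seed` set inside `params` is overridden).
#' @param taxon_group,direction manifest metadata (recycled).
#' @param island_range_km2,mainland_range_km2 optional range areas (recycled).
#' @param polymorphism_only passed to [simulate_comparison()].
#' @return path to the manifest, with the per-comparison truth records as
#'   attribute `"truth"`.
#' @export
simulate_dataset <- function(n_comparisons, params = scenario_params(), dir,
                             seed = 1L, taxon_group = "bird",
                             direction = "mainland_to_island",
                             island_range_km2 = NA_real_,
                             mainland_range_km2 = NA_real_,
                             polymorphism_only = FALSE) {
  stopifnot(n_comparisons >= 1L)
  if (inherits(params, "scenario_params"))
    params <- rep(list(params), n_comparisons)
  stopifnot(length(params) == n_comparisons)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  taxon_group <- rep_len(taxon_group, n_comparisons)
  direction <- rep_len(direction, n_comparisons)
  island_range_km2 <- rep_len(island_range_km2, n_comparisons)
  mainland_range_km2 <- rep_len(mainland_range_km2, n_comparisons)

  rows <- vector("list", n_comparisons)
  truths <- vector("list", n_comparisons)
  for (i in seq_len(n_comparisons)) {
    p <- params[[i]]
    p$seed <- (as.integer(seed) * 7919L + i * 104729L) %% 2147483647L
    id <- sprintf("cmp%03d", i)
    sim <- simulate_comparison(p, polymorphism_only = polymorphism_only,
                               id_prefix = id)
    f_isl <- sprintf("%s_island.fa", id)
    f_mnl <- sprintf("%s_mainland.fa", id)
    write_codon_alignment(sim$island, file.path(dir, f_isl))
    write_codon_alignment(sim$mainland, file.path(dir, f_mnl))
    f_div <- ""
    if (!is.null(sim$triplet)) {
      f_div <- sprintf("%s_divergence.fa", id)
      tri <- sim$triplet
      write_codon_alignment(tri, file.path(dir, f_div))
    }
    jsonlite::write_json(sim$truth, file.path(dir, sprintf("%s_truth.json", id)),
                         auto_unbox = TRUE, digits = NA, null = "null")
    truths[[i]] <- sim$truth
    rows[[i]] <- data.frame(
      comparison_id = id,
      island_species = sprintf("%s_isl", id),
      mainland_species = sprintf("%s_main", id),
      outgroup_species = sprintf("%s_out", id),
      genome = p$genome, taxon_group = taxon_group[i],
      direction = direction[i], genetic_code = p$genetic_code,
      island_range_km2 = ifelse(is.na(island_range_km2[i]), "",
                                format(island_range_km2[i])),
      mainland_range_km2 = ifelse(is.na(mainland_range_km2[i]), "",
                                  format(mainland_range_km2[i])),
      polymorphism_files = sprintf("%s_isl=%s;%s_main=%s", id, f_isl, id, f_mnl),
      divergence_file = f_div,
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.tsv")
  write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  attr(manifest_path, "truth") <- truths
  manifest_path
}
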