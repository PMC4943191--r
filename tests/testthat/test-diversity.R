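test_that("NG86 site counts match brute-force enumeration on all sense codons", {
  for (code in c("standard", "vertebrate_mitochondrial")) {
    for (codon in sense_codons(code)) {
      expect_equal(unname(count_sites(codon, code)),
                   oracle_count_sites(codon, code),
                   tolerance = 1e-12,
                   label = paste(code, codon))
    }
  }
  expect_equal(unname(count_sites("TGG")), c(0, 3))   # tryptophan
  expect_equal(unname(count_sites("GGG")), c(1, 2))   # glycine
  expect_error(count_sites("TAA"), "stop")
  expect_error(count_sites("TNA"), "ambiguous|invalid")
})

test_that("pathway classification matches recursive enumeration", {
  expect_equal(unname(classify_pair_diffs("AAA", "AAA")), c(0, 0))
  expect_equal(unname(classify_pair_diffs("TTT", "TTC")), c(1, 0))
  expect_equal(unname(classify_pair_diffs("TTT", "GTA")),
               oracle_classify("TTT", "GTA"))
  withr::local_seed(21)
  for (k in 1:150) {
    code <- sample(c("standard", "invertebrate_mitochondrial"), 1)
    pair <- random_sense_codon(2, code)
    got <- suppressWarnings(unname(classify_pair_diffs(pair[1], pair[2], code)))
    want <- oracle_classify(pair[1], pair[2], code)
    expect_equal(got, want, tolerance = 1e-12,
                 label = paste(code, pair[1], pair[2]))
    if (!anyNA(want) && sum(want) > 0)
      expect_equal(sum(got), sum(strsplit(pair[1], "")[[1]] !=
                                   strsplit(pair[2], "")[[1]]))
  }
})

test_that("diversity_stats hand-checked examples", {
  # identical sequences: everything zero
  d0 <- diversity_stats(codon_alignment(c(a = "ATGGCT", b = "ATGGCT")))
  expect_equal(d0$pi_S, 0)
  expect_equal(d0$pi_N, 0)
  expect_equal(d0$n_syn_poly + d0$n_nonsyn_poly, 0)

  # one synonymous difference in one codon
  d1 <- diversity_stats(codon_alignment(c(a = "TTT", b = "TTC")))
  sites_mean <- mean(c(count_sites("TTT")[1], count_sites("TTC")[1]))
  expect_equal(d1$pi_S, 1 / sites_mean)
  expect_equal(d1$pi_N, 0)
  expect_equal(d1$n_syn_poly, 1)

  # biallelic synonymous site at frequency 2/4: 4 of 6 pairs differ
  d2 <- diversity_stats(codon_alignment(
    c(a = "TTTAAA", b = "TTTAAA", c = "TTCAAA", d = "TTCAAA")))
  expect_equal(d2$pi_S, (4 / 6) / d2$syn_sites)
  expect_equal(d2$pi_N, 0)

  expect_error(diversity_stats(codon_alignment(c(a = "ATG"))), "at least 2")
})

test_that("diversity_stats matches exhaustive brute force on random tiny alignments", {
  withr::local_seed(5)
  for (k in 1:25) {
    n <- sample(2:4, 1)
    L <- sample(2:4, 1)
    base <- random_cds(L)
    seqs <- vapply(seq_len(n), function(i) mutate_cds(base, sample(0:3, 1)), "")
    aln <- codon_alignment(seqs, ids = paste0("s", seq_len(n)))
    got <- suppressWarnings(diversity_stats(aln))
    want <- oracle_diversity(seqs)
    expect_equal(got$pi_S, want$pi_S, tolerance = 1e-12)
    expect_equal(got$pi_N, want$pi_N, tolerance = 1e-12)
    expect_equal(got$pi_total, want$pi_total, tolerance = 1e-12)
  }
})

test_that("site-count conservation and permutation invariance", {
  withr::local_seed(9)
  seqs <- vapply(1:5, function(i) mutate_cds(random_cds(30), 4), "")
  aln <- codon_alignment(seqs, ids = paste0("s", 1:5))
  d <- diversity_stats(aln)
  expect_equal(d$syn_sites + d$nonsyn_sites, 3 * d$n_codons_used,
               tolerance = 1e-9)
  perm <- sample(5)
  d2 <- diversity_stats(codon_alignment(seqs[perm], ids = paste0("s", perm)))
  expect_equal(d$pi_S, d2$pi_S)
  expect_equal(d$pi_N, d2$pi_N)
  expect_equal(d$pi_total, d2$pi_total)
})

test_that("aggregate_species is an unweighted mean and permutation-invariant", {
  withr::local_seed(13)
  stats <- lapply(1:3, function(i) {
    seqs <- vapply(1:3, function(j) mutate_cds(random_cds(20), 3), "")
    diversity_stats(codon_alignment(seqs, ids = paste0("s", 1:3)))
  })
  expect_identical(aggregate_species(stats[1]), stats[[1]])
  agg <- aggregate_species(stats)
  expect_equal(agg$pi_S, mean(vapply(stats, `[[`, 0, "pi_S")))
  agg_perm <- aggregate_species(stats[c(3, 1, 2)])
  expect_equal(agg$pi_S, agg_perm$pi_S)
  expect_equal(agg$pi_N, agg_perm$pi_N)
  expect_error(aggregate_species(list()), "empty")
})

test_that("E[pi_S] is unbiased by the number of chromosomes sampled", {
  # neutral simulations at n = 2, 5, 10: means agree within Monte-Carlo error
  reps <- 120
  means <- vapply(c(2, 5, 10), function(n) {
    pis <- vapply(seq_len(reps), function(i) {
      p <- scenario_params(nonsyn_neutral_fraction = 1, nonsyn_weak_fraction = 0,
                           n_codons = 150,
                           sample_sizes = c(island = n, mainland = 2),
                           seed = 7000 + 17 * i + n)
      diversity_stats(simulate_comparison(p, polymorphism_only = TRUE)$island)$pi_S
    }, 0)
    c(mean(pis), sd(pis) / sqrt(reps))
  }, c(0, 0))
  for (a in 1:2) for (b in (a + 1):3) {
    z <- abs(means[1, a] - means[1, b]) /
      sqrt(means[2, a]^2 + means[2, b]^2)
    expect_lt(z, 4)
  }
})
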