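pad <- strrep("GGAAGT", 10)  # invariant 20-codon background, stop-free

triplet_of <- function(i, m, o, code = "standard") {
  codon_alignment(c(island = paste0(i, pad), mainland = paste0(m, pad),
                    outgroup = paste0(o, pad)),
                  genetic_code = code)
}

test_that("parsimony assignment: forced two-against-one patterns", {
  z <- assign_lineage_changes(triplet_of("GGA", "GGA", "GGA"))
  expect_equal(sum(z$syn_changes) + sum(z$nonsyn_changes), 0)

  # island TTC vs shared TTT: one synonymous change on the island branch
  z <- assign_lineage_changes(triplet_of("TTC", "TTT", "TTT"))
  expect_equal(unname(z$syn_changes["island"]), 1)
  expect_equal(sum(z$nonsyn_changes), 0)
  expect_equal(unname(z$syn_changes["mainland"] + z$syn_changes["outgroup"]), 0)

  # shared island+mainland change polarized onto the outgroup branch
  z <- assign_lineage_changes(triplet_of("TTT", "TTT", "TTC"))
  expect_equal(unname(z$syn_changes["outgroup"]), 1)

  # mainland-only non-synonymous change
  z <- assign_lineage_changes(triplet_of("TTT", "CTT", "TTT"))
  expect_equal(unname(z$nonsyn_changes["mainland"]), 1)
  expect_equal(sum(z$syn_changes), 0)

  expect_error(assign_lineage_changes(codon_alignment(
    c(a = "TTT", b = "TTT"))), "exactly 3")
})

test_that("parsimony assignment matches exhaustive ancestral enumeration", {
  withr::local_seed(31)
  for (k in 1:60) {
    cods <- matrix(random_sense_codon(9), nrow = 3)  # 3 taxa x 3 codons
    seqs <- apply(cods, 1, paste0, collapse = "")
    tri <- codon_alignment(c(island = seqs[1], mainland = seqs[2],
                             outgroup = seqs[3]))
    got <- suppressWarnings(assign_lineage_changes(tri))
    want_syn <- c(0, 0, 0); want_non <- c(0, 0, 0)
    for (j in 1:3) {
      col <- oracle_parsimony_column(cods[1, j], cods[2, j], cods[3, j])
      if (is.null(col)) next
      want_syn <- want_syn + col[, 1]
      want_non <- want_non + col[, 2]
    }
    expect_equal(unname(got$syn_changes), want_syn, tolerance = 1e-12)
    expect_equal(unname(got$nonsyn_changes), want_non, tolerance = 1e-12)
  }
})

test_that("Jukes-Cantor correction: closed form, saturation guards", {
  expect_equal(jc_correct(0), 0)
  expect_equal(jc_correct(0.1), -0.75 * log(1 - 0.4 / 3))
  expect_equal(jc_correct(0.1), 0.107326, tolerance = 1e-4)
  expect_error(jc_correct(0.75), "saturation")
  expect_warning(jc_correct(0.65), "unreliable")
})

test_that("branch_rates: rates, omega and the dS = 0 flag", {
  ch <- list(syn_changes = c(island = 2, mainland = 2, outgroup = 0),
             nonsyn_changes = c(island = 2, mainland = 0, outgroup = 1))
  br <- branch_rates(ch, syn_sites = 20, nonsyn_sites = 40)
  isl <- br[br$branch == "island", ]
  expect_equal(isl$dS, jc_correct(0.1))
  expect_equal(isl$dN, jc_correct(0.05))
  # equal per-site proportions give omega = 1
  br1 <- branch_rates(list(syn_changes = c(island = 2, mainland = 0, outgroup = 0),
                           nonsyn_changes = c(island = 4, mainland = 0, outgroup = 0)),
                      20, 40)
  expect_equal(br1$omega[br1$branch == "island"], 1)
  # dS = 0: omega flagged undefined, not zero
  out <- br[br$branch == "outgroup", ]
  expect_true(is.na(out$omega))
  expect_false(out$omega_defined)
  expect_error(branch_rates(ch, 0, 40), "positive")
})

test_that("island/mainland label swap exactly swaps the branch outputs", {
  withr::local_seed(41)
  sim <- simulate_comparison(scenario_params(n_codons = 120, seed = 99))
  tri <- sim$triplet
  fwd <- divergence_stats(tri)
  swapped <- codon_alignment(tri$seq[c(2, 1, 3)],
                             ids = c("m", "i", "o"),
                             genome = tri$genome,
                             genetic_code = tri$genetic_code)
  rev <- divergence_stats(swapped)
  expect_equal(fwd[fwd$branch == "island", -1],
               rev[rev$branch == "mainland", -1], ignore_attr = TRUE)
  expect_equal(fwd[fwd$branch == "mainland", -1],
               rev[rev$branch == "island", -1], ignore_attr = TRUE)
  expect_equal(fwd[fwd$branch == "outgroup", -1],
               rev[rev$branch == "outgroup", -1], ignore_attr = TRUE)
})

test_that("representative_sequence: identity, majority, documented tie-break", {
  one <- codon_alignment(c(a = "ATGGCT"))
  expect_equal(representative_sequence(one), "ATGGCT")
  maj <- codon_alignment(c(a = "ATG", b = "ATG", c = "GTG"))
  expect_equal(representative_sequence(maj), "ATG")
  tie <- codon_alignment(c(a = "GTG", b = "ATG"))
  expect_message(cons <- representative_sequence(tie), "tie")
  expect_equal(cons, "GTG")  # first-listed sequence wins
})

test_that("simulation consistency: omega ~ 1 neutral, < 1 under purifying selection, dS tracks branch length", {
  reps <- 40
  run <- function(f_neutral, f_weak) {
    vals <- vapply(seq_len(reps), function(i) {
      p <- scenario_params(nonsyn_neutral_fraction = f_neutral,
                           nonsyn_weak_fraction = f_weak,
                           sample_sizes = c(island = 2, mainland = 2),
                           seed = 5000 + i)
      d <- divergence_stats(simulate_comparison(p)$triplet)
      c(omega = mean(d$omega[1:2]), dS = mean(d$dS[1:2]))
    }, c(0, 0))
    rowMeans(vals)
  }
  neutral <- run(1, 0)
  purifying <- run(0.2, 0)
  expect_gt(neutral["omega"], 0.85)
  expect_lt(abs(neutral["omega"] - 1), 0.15)
  expect_lt(purifying["omega"], 0.5)
  # island/mainland branch dS ~ split_time * theta/2 (with JC correction and
  # within-deme coalescent time this sits near 0.3 for the defaults)
  expect_gt(neutral["dS"], 0.2)
  expect_lt(neutral["dS"], 0.45)
})
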