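write_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

test_that("frame validation: terminal stop trim, frame and stop errors", {
  p <- write_fasta(c(a = "ATGGCTTAA", b = "ATGGCTTAA"))
  aln <- read_codon_alignment(p, genetic_code = "standard")
  expect_equal(length(aln$ids), 2L)
  expect_equal(aln$n_codons, 2L)        # TAA trimmed
  expect_equal(sum(aln$masked), 0L)

  expect_error(read_codon_alignment(write_fasta(c(a = "ATGTA")),
                                    genetic_code = "standard"),
               "frame error")
  expect_error(read_codon_alignment(write_fasta(c(a = "ATGTAAGGG")),
                                    genetic_code = "standard"),
               "codon 2")
  expect_error(codon_alignment(c(a = "ATGGCT", b = "ATG")), "ragged")
  expect_error(codon_alignment(c(a = "ATGXCT")), "outside")
})

test_that("genetic codes change what counts as a stop", {
  # TGA is a stop under the standard code but tryptophan in vertebrate mito
  expect_error(codon_alignment(c(a = "ATGTGAGGG"), genetic_code = "standard"),
               "internal stop")
  aln <- codon_alignment(c(a = "ATGTGAGGG"), genome = "mitochondrial",
                         genetic_code = "vertebrate_mitochondrial")
  expect_equal(aln$n_codons, 3L)
  # default code follows the genome tag
  expect_equal(default_genetic_code("mitochondrial"), "vertebrate_mitochondrial")
  expect_equal(default_genetic_code("nuclear"), "standard")
  expect_equal(default_genetic_code("chloroplast"), "plant_plastid")
})

test_that("masking: gap or N anywhere masks the codon column for everyone, monotonically", {
  aln <- codon_alignment(c(a = "ATGGCTAAA", b = "ATG-CTAAA"))
  expect_equal(aln$masked, c(FALSE, TRUE, FALSE))
  # adding a gap to another sequence never unmasks anything
  withr::local_seed(11)
  for (k in 1:20) {
    n <- sample(2:4, 1)
    seqs <- vapply(seq_len(n), function(i) random_cds(6), "")
    a0 <- codon_alignment(seqs, ids = paste0("s", 1:n))
    i <- sample(n, 1); j <- sample(6, 1)
    seqs2 <- seqs
    substr(seqs2[i], 3 * j - 2, 3 * j - 2) <- "-"
    a1 <- codon_alignment(seqs2, ids = paste0("s", 1:n))
    expect_true(all(a1$masked >= a0$masked))
    expect_true(a1$masked[j])
  }
})

test_that("read -> write -> read round trip is byte-exact", {
  withr::local_seed(3)
  seqs <- setNames(vapply(1:4, function(i) random_cds(40), ""),
                   paste0("sp", 1:4))
  p1 <- write_fasta(seqs)
  a1 <- read_codon_alignment(p1)
  p2 <- tempfile(fileext = ".fa")
  write_codon_alignment(a1, p2)
  a2 <- read_codon_alignment(p2)
  expect_identical(a1$ids, a2$ids)
  expect_identical(a1$seq, a2$seq)
  expect_identical(a1$seq, unname(seqs))
})

test_that("concatenate_loci: additive length, identity, associativity, error cases", {
  withr::local_seed(7)
  ids <- c("A", "B", "C")
  mk <- function(ncod) codon_alignment(
    setNames(vapply(1:3, function(i) random_cds(ncod), ""), ids))
  a <- mk(100); b <- mk(150); c3 <- mk(30)
  ab <- concatenate_loci(list(a, b))
  expect_equal(ab$length_nt, 750L)  # 300 + 450
  expect_identical(concatenate_loci(list(a)), a)
  left <- concatenate_loci(list(concatenate_loci(list(a, b)), c3))
  right <- concatenate_loci(list(a, concatenate_loci(list(b, c3))))
  expect_identical(left$seq, right$seq)
  # per-locus masking is preserved codon-wise
  g <- codon_alignment(c(A = "ATG-CTAAA", B = "ATGGCTAAA", C = "ATGGCTAAA"))
  ag <- concatenate_loci(list(a, g))
  expect_equal(ag$masked, c(a$masked, g$masked))
  nuc <- codon_alignment(setNames(vapply(1:3, function(i) random_cds(10), ""),
                                  ids), genome = "mitochondrial",
                         genetic_code = "standard")
  expect_error(concatenate_loci(list(a, nuc)), "genome|genetic code")
  expect_error(concatenate_loci(list(a, codon_alignment(c(X = random_cds(5))))),
               "species sets")
})

test_that("manifest parsing and validation", {
  tsv <- function(lines, extra_header = NULL) {
    p <- tempfile(fileext = ".tsv")
    hd <- paste(c("comparison_id", "island_species", "mainland_species",
                  "outgroup_species", "genome", "taxon_group", "direction",
                  "island_range_km2", extra_header), collapse = "\t")
    writeLines(c(hd, lines), p)
    p
  }
  row1 <- "c1\tA\tB\tC\tmitochondrial\tbird\tmainland_to_island\t"
  m <- read_manifest(tsv(row1))
  expect_s3_class(m, "comparison_manifest")
  expect_equal(m[[1]]$island_species, "A")
  expect_equal(m[[1]]$genetic_code, "vertebrate_mitochondrial")
  expect_true(is.na(m[[1]]$island_range_km2))  # absent, not zero
  expect_equal(m[[1]]$group_id, "c1")

  expect_error(read_manifest(tsv(c(row1, row1))), "duplicate comparison_id")
  expect_error(read_manifest(
    tsv("c1\tA\tB\tC\tplasmid\tbird\tmainland_to_island\t")), "genome")
  expect_error(read_manifest(
    tsv("c1\tA\tB\tC\tnuclear\tbird\tmainland_to_island\t-5")),
    "nonnegative")
  expect_error(read_manifest(
    tsv("c1\t\tB\tC\tnuclear\tbird\tmainland_to_island\t")),
    "at least one island")
  expect_warning(read_manifest(
    tsv("c1\tA\tB\tC\tnuclear\tbird\tmainland_to_island\t\tx",
        extra_header = "mystery_column")), "unknown column")
  # species lists and per-row genetic code override
  m2 <- read_manifest(tsv(
    "c2\tA1,A2\tB1,B2\tC\tmitochondrial\tinvertebrate\tmainland_to_island\t12.5",
    extra_header = NULL))
  expect_equal(m2[[1]]$island_species, c("A1", "A2"))
  expect_equal(m2[[1]]$island_range_km2, 12.5)
})
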