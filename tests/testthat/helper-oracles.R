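# Independent brute-force oracles. Deliberately written with different
# machinery from the package internals (string manipulation + Biostrings
# translation + recursive enumeration) so agreement is informative.

BASES4 <- c("A", "C", "G", "T")

oracle_code <- function(genetic_code) {
  id <- switch(genetic_code,
               standard = "1", vertebrate_mitochondrial = "2",
               invertebrate_mitochondrial = "5", plant_plastid = "11")
  Biostrings::getGeneticCode(id)
}

oracle_translate <- function(codon, gc) unname(gc[[codon]])

oracle_mutants <- function(codon, pos) {
  cur <- substr(codon, pos, pos)
  vapply(setdiff(BASES4, cur), function(b) {
    x <- codon
    substr(x, pos, pos) <- b
    x
  }, "")
}

# NG86 fractional site counts by direct mutant enumeration
oracle_count_sites <- function(codon, genetic_code = "standard") {
  gc <- oracle_code(genetic_code)
  aa0 <- oracle_translate(codon, gc)
  stopifnot(aa0 != "*")
  syn <- 0
  for (pos in 1:3) {
    muts <- oracle_mutants(codon, pos)
    aas <- vapply(muts, oracle_translate, "", gc = gc)
    nonstop <- aas != "*"
    if (any(nonstop)) syn <- syn + sum(aas[nonstop] == aa0) / sum(nonstop)
  }
  c(syn, 3 - syn)
}

# pathway classification by recursive enumeration of orderings
oracle_classify <- function(a, b, genetic_code = "standard") {
  gc <- oracle_code(genetic_code)
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (!length(pos)) return(c(0, 0))
  paths <- list()
  recurse <- function(cur, remaining, syn, non) {
    if (!length(remaining)) {
      paths[[length(paths) + 1L]] <<- c(syn, non)
      return()
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (oracle_translate(nxt, gc) == "*") next
      ds <- oracle_translate(cur, gc) == oracle_translate(nxt, gc)
      recurse(nxt, setdiff(remaining, p), syn + ds, non + !ds)
    }
  }
  recurse(a, pos, 0L, 0L)
  if (!length(paths)) return(c(NA_real_, NA_real_))
  colMeans(do.call(rbind, paths))
}

# exhaustive diversity on tiny alignments: every pair, codon, pathway
oracle_diversity <- function(seqs, genetic_code = "standard") {
  n <- length(seqs)
  L <- nchar(seqs[1]) / 3
  codons <- lapply(seqs, function(s)
    substring(s, 3 * seq_len(L) - 2, 3 * seq_len(L)))
  syn_tot <- 0; non_tot <- 0; nt_tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    np <- np + 1
    for (k in seq_len(L)) {
      cls <- oracle_classify(codons[[i]][k], codons[[j]][k], genetic_code)
      if (anyNA(cls)) next
      syn_tot <- syn_tot + cls[1]; non_tot <- non_tot + cls[2]
      nt_tot <- nt_tot + sum(strsplit(codons[[i]][k], "")[[1]] !=
                               strsplit(codons[[j]][k], "")[[1]])
    }
  }
  sites <- vapply(codons, function(cs)
    sum(vapply(cs, function(c) oracle_count_sites(c, genetic_code)[1], 0)), 0)
  list(pi_S = (syn_tot / np) / mean(sites),
       pi_N = (non_tot / np) / mean(3 * L - sites),
       pi_total = (nt_tot / np) / (3 * L))
}

# exhaustive parsimony on a 3-codon-state column: enumerate every sense
# ancestral codon, keep minimal-total-change ancestors, average branch splits
oracle_parsimony_column <- function(ci, cm, co, genetic_code = "standard") {
  gc <- oracle_code(genetic_code)
  sense <- names(gc)[gc != "*"]
  ndiff <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  tot <- vapply(sense, function(a) ndiff(a, ci) + ndiff(a, cm) + ndiff(a, co), 0)
  anc <- sense[tot == min(tot)]
  rows <- list()
  for (a in anc) {
    cls <- rbind(oracle_classify(a, ci, genetic_code),
                 oracle_classify(a, cm, genetic_code),
                 oracle_classify(a, co, genetic_code))
    if (anyNA(cls)) next
    rows[[length(rows) + 1L]] <- cls
  }
  if (!length(rows)) return(NULL)
  Reduce(`+`, rows) / length(rows)  # 3x2: branch (i,m,o) x (syn, nonsyn)
}

# Wilcoxon signed-rank p-value by explicit enumeration of all 2^m sign vectors
oracle_wilcoxon <- function(values, center = 0.5, tail = "two_sided") {
  d <- values - center
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  switch(tail, less = p_le, greater = p_ge,
         two_sided = min(1, 2 * min(p_le, p_ge)))
}

# Spearman coefficient by direct rank-and-moment computation
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

sense_codons <- function(genetic_code = "standard") {
  gc <- oracle_code(genetic_code)
  names(gc)[gc != "*"]
}

random_sense_codon <- function(n, genetic_code = "standard") {
  sample(sense_codons(genetic_code), n, replace = TRUE)
}

# random in-frame stop-free sequence of n codons
random_cds <- function(n, genetic_code = "standard") {
  paste0(random_sense_codon(n, genetic_code), collapse = "")
}

# random mutant of a codon-structured sequence avoiding stops
mutate_cds <- function(seq, n_mut, genetic_code = "standard") {
  gc <- oracle_code(genetic_code)
  for (k in seq_len(n_mut)) {
    repeat {
      i <- sample.int(nchar(seq), 1)
      b <- sample(setdiff(BASES4, substr(seq, i, i)), 1)
      cand <- seq
      substr(cand, i, i) <- b
      cs <- ceiling(i / 3)
      codon <- substr(cand, 3 * cs - 2, 3 * cs)
      if (oracle_translate(codon, gc) != "*") { seq <- cand; break }
    }
  }
  seq
}
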