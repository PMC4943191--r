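# Codon lookup machinery.
#
# All codon-level computation in the package runs on integer codon indices
# 1..64 with bases ordered T, C, A, G (index = (b1-1)*16 + (b2-1)*4 + b3).
# For each genetic code a table of precomputed lookups is built once and
# cached: amino acids, stop flags, Nei-Gojobori fractional site counts, and
# 64 x 64 matrices of pathway-averaged synonymous/non-synonymous difference
# counts. Translation tables themselves come from Biostrings.

.BASES <- c("T", "C", "A", "G")

# NCBI translation table ids for the supported codes
.CODE_IDS <- c(standard = "1",
               vertebrate_mitochondrial = "2",
               invertebrate_mitochondrial = "5",
               plant_plastid = "11")

.tbl_cache <- new.env(parent = emptyenv())

# base-index triplets for codons 1..64
.codon_grid <- local({
  g <- expand.grid(b3 = 1:4, b2 = 1:4, b1 = 1:4)
  cbind(g$b1, g$b2, g$b3)
})

.codon_strs <- apply(.codon_grid, 1L, function(b) paste0(.BASES[b], collapse = ""))

codon_index <- function(b1, b2, b3) (b1 - 1L) * 16L + (b2 - 1L) * 4L + b3

# permutations of 1..k for pathway enumeration
.perms <- list(matrix(1L, 1, 1),
               rbind(c(1L, 2L), c(2L, 1L)),
               rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                     c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

# Pathway-average the syn/nonsyn split of the differences between two sense
# codons: enumerate all orderings of the differing positions, drop orderings
# that pass through a stop codon, average step classifications over the rest.
# Returns c(syn, nonsyn) or c(NA, NA) when every ordering is blocked.
.classify_pair <- function(ca, cb, aa, is_stop) {
  ba <- .codon_grid[ca, ]
  bb <- .codon_grid[cb, ]
  pos <- which(ba != bb)
  k <- length(pos)
  if (k == 0L) return(c(0, 0))
  perms <- .perms[[k]]
  tot_syn <- 0
  tot_non <- 0
  n_ok <- 0L
  for (r in seq_len(nrow(perms))) {
    cur <- ba
    syn <- 0L
    non <- 0L
    ok <- TRUE
    for (p in pos[perms[r, ]]) {
      nxt <- cur
      nxt[p] <- bb[p]
      ci_cur <- codon_index(cur[1], cur[2], cur[3])
      ci_nxt <- codon_index(nxt[1], nxt[2], nxt[3])
      if (is_stop[ci_nxt]) { ok <- FALSE; break }
      if (aa[ci_cur] == aa[ci_nxt]) syn <- syn + 1L else non <- non + 1L
      cur <- nxt
    }
    if (ok) {
      tot_syn <- tot_syn + syn
      tot_non <- tot_non + non
      n_ok <- n_ok + 1L
    }
  }
  if (n_ok == 0L) return(c(NA_real_, NA_real_))
  c(tot_syn / n_ok, tot_non / n_ok)
}

# Build (or fetch from cache) the full lookup table for one genetic code.
codon_table <- function(genetic_code = "standard") {
  genetic_code <- check_enum(genetic_code, GENETIC_CODES, "genetic_code")
  if (!is.null(.tbl_cache[[genetic_code]])) return(.tbl_cache[[genetic_code]])

  gc_map <- Biostrings::getGeneticCode(.CODE_IDS[[genetic_code]])
  aa <- unname(gc_map[.codon_strs])
  is_stop <- aa == "*"
  sense <- which(!is_stop)

  # single-mutant neighbours: mut_idx[c, p, a] is the codon obtained by
  # replacing position p of codon c with its a-th alternative base (a = 1..3,
  # in T,C,A,G order skipping the current base); nb_idx[c, p, b] addresses the
  # mutant by target base (NA when b is the current base).
  mut_idx <- array(NA_integer_, c(64L, 3L, 3L))
  nb_idx <- array(NA_integer_, c(64L, 3L, 4L))
  for (ci in 1:64) {
    b <- .codon_grid[ci, ]
    for (p in 1:3) {
      alts <- (1:4)[-b[p]]
      for (a in 1:3) {
        nb <- b
        nb[p] <- alts[a]
        mi <- codon_index(nb[1], nb[2], nb[3])
        mut_idx[ci, p, a] <- mi
        nb_idx[ci, p, alts[a]] <- mi
      }
    }
  }

  # NG86 fractional site counts: at each position the synonymous fraction is
  # (# synonymous single-nt mutants) / (# non-stop mutants); stop mutants are
  # excluded from the denominator.
  syn_sites <- rep(NA_real_, 64L)
  for (ci in sense) {
    s <- 0
    for (p in 1:3) {
      muts <- mut_idx[ci, p, ]
      keep <- !is_stop[muts]
      denom <- sum(keep)
      if (denom > 0)
        s <- s + sum(aa[muts[keep]] == aa[ci]) / denom
    }
    syn_sites[ci] <- s
  }
  nonsyn_sites <- 3 - syn_sites

  # raw nucleotide differences between any two codons
  ndiff <- matrix(0L, 64L, 64L)
  for (p in 1:3) {
    same <- outer(.codon_grid[, p], .codon_grid[, p], "==")
    ndiff <- ndiff + !same
  }

  # pathway-averaged classification for all sense x sense pairs
  syn_diff <- matrix(NA_real_, 64L, 64L)
  nonsyn_diff <- matrix(NA_real_, 64L, 64L)
  for (ca in sense) {
    syn_diff[ca, ca] <- 0
    nonsyn_diff[ca, ca] <- 0
    for (cb in sense) {
      if (cb <= ca) next
      cls <- .classify_pair(ca, cb, aa, is_stop)
      syn_diff[ca, cb] <- cls[1]
      syn_diff[cb, ca] <- cls[1]
      nonsyn_diff[ca, cb] <- cls[2]
      nonsyn_diff[cb, ca] <- cls[2]
    }
  }

  # per-codon count of stop single-mutants (used for the generator's
  # analytic expected synonymous rate)
  n_stop_mut <- vapply(1:64, function(ci) sum(is_stop[mut_idx[ci, , ]]), 0L)
  # raw count of synonymous single-mutants
  n_syn_mut <- vapply(1:64, function(ci) {
    muts <- mut_idx[ci, , ]
    sum(!is_stop[muts] & aa[muts] == aa[ci])
  }, 0L)

  tbl <- list(genetic_code = genetic_code, aa = aa, is_stop = is_stop,
              sense = sense, codon_strs = .codon_strs, codon_grid = .codon_grid,
              mut_idx = mut_idx, nb_idx = nb_idx,
              syn_sites = syn_sites, nonsyn_sites = nonsyn_sites,
              ndiff = ndiff, syn_diff = syn_diff, nonsyn_diff = nonsyn_diff,
              n_stop_mut = n_stop_mut, n_syn_mut = n_syn_mut)
  .tbl_cache[[genetic_code]] <- tbl
  tbl
}

# codon string -> index (NA when the triplet contains anything but ACGT)
codon_str_to_index <- function(codons) {
  i <- match(toupper(codons), .codon_strs)
  i
}

# DNA string (length multiple of 3) -> integer codon vector with NA for
# masked codons (gap or N anywhere in the triplet)
dna_to_codons <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- !(chars %in% c(.BASES, "N", "-"))
  if (any(bad))
    stop("sequence contains characters outside {A,C,G,T,N,-}: ",
         paste(unique(chars[bad]), collapse = ", "), call. = FALSE)
  b <- match(chars, .BASES)  # NA for N or -
  n_cod <- length(b) %/% 3L
  m <- matrix(b, nrow = 3L)
  idx <- codon_index(m[1, ], m[2, ], m[3, ])
  idx
}

codons_to_dna <- function(idx) paste0(.codon_strs[idx], collapse = "")
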