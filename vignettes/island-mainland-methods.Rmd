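---
title: "Methods: paired island–mainland molecular evolution statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired island-mainland molecular evolution statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(islemol)
```

# The design

Each observation is one phylogenetically independent island–mainland species
pair (optionally clades of several species each) with an outgroup. Because
absolute statistics vary enormously across taxa, every comparison is reduced
to a relative island value

$$X' = \frac{X_\mathrm{island}}{X_\mathrm{island} + X_\mathrm{mainland}},$$

which is 0.5 when island and mainland are equal and is undefined (and the
comparison excluded, with a logged count) only when both sides are zero.
Dataset-level inference is a Wilcoxon signed-rank test of symmetry about 0.5
and a percentile bootstrap CI of the mean relative value. The paired design
cancels shared life-history effects; the only modelling assumption carried by
the test is exchangeability of the island and mainland labels under the null.

# Polymorphism statistics

Within-species codon alignments are validated (in-frame, no internal stops
under the declared genetic code; terminal stops trimmed) and any codon column
containing a gap or `N` in *any* sequence is masked for all sequences
(complete deletion at codon granularity). Complete deletion keeps the site
denominators identical across sequences, which the diversity estimators
assume; the alternative — pairwise deletion — would make $\pi$ a ratio of
quantities computed on different site sets.

Synonymous and non-synonymous opportunity is counted by the Nei–Gojobori
(1986) fractional-site scheme: at each codon position, the synonymous
fraction is the number of synonymous single-nucleotide mutants divided by the
number of non-stop mutants. Differences between codons are classified by
pathway averaging: all orderings of the differing positions are enumerated,
orderings passing through a stop codon are discarded, and synonymous /
non-synonymous step counts are averaged over the rest (equal weights, no
transition/transversion weighting — the simplest defensible estimator; codon
pairs whose every pathway is blocked are skipped with a warning). Then

$$\pi_S = \frac{\text{mean pairwise synonymous differences}}
               {\text{mean per-sequence synonymous sites}},$$

and $\pi_N$ analogously. Nucleotide diversity rather than polymorphism
counts is used throughout because $\pi$ is unbiased by the number of
chromosomes sampled (the test suite checks this on simulated data at
n = 2, 5, 10). No multiple-hit correction is applied to $\pi$: within-species
distances are small. Multi-species clades and multi-locus species are
averaged arithmetically (loci within species, then species within clade), so
each comparison contributes one island and one mainland value per genome.

# Divergence statistics

Lineage-specific $d_N$, $d_S$ and $\omega$ for the island, mainland and
outgroup branches are estimated by a counting method: each unmasked codon
pattern of the (island, mainland, outgroup) triplet is resolved by parsimony
— the codon shared by two taxa is ancestral, so a change shared by island and
mainland is assigned to the outgroup branch; three-way differences are
resolved by minimum-change enumeration over all sense ancestral codons with
ties split equally. Changes are pathway-classified, converted to proportions
per NG86 site (the mean site totals of the three sequences), and
Jukes–Cantor corrected, $d = -\tfrac34\ln(1 - \tfrac43 p)$.

**This is a deliberate substitution.** The analysis this package
re-implements used maximum-likelihood branch models (codeml) for this step;
that machinery is third-party software, not a described algorithm, and is out
of scope here. Parsimony + NG86 + JC is fully specified, desk-scale, and
adequate at the low-to-moderate divergences typical of congeneric
island–mainland pairs; it will misassign changes when homoplasy is common,
so a saturation guard warns at $p \ge 0.6$ and errors at $p \ge 3/4$ (where
the JC correction diverges). The substitution is stamped into every output's
provenance block.

When a clade has several species, the default (`divergence_mode =
"average"`) computes per-species triplets against the consensus of the sister
clade and averages $d_N$ and $d_S$ separately across species, recomputing
$\omega$ from the averages; whether one should average $\omega$ itself or its
parts is genuinely ambiguous, and separate averaging was chosen because
per-species $\omega$ is undefined whenever a single species has $d_S = 0$.
A `"consensus"` mode (one consensus-vs-consensus triplet) is the fallback.
Consensus ties are broken by the first-listed sequence and logged.

# Selection and N_e statistics

- $\pi_N/(\pi_N+\pi_S)$: efficiency of purifying selection on segregating
  variation; undefined only when both diversities are zero.
- $\mathrm{DoS} = d_N/(d_N+d_S) - \pi_N/(\pi_N+\pi_S)$: positive when
  positive selection dominates, negative when slightly deleterious
  polymorphism predominates; defined when there is at least one substitution
  and one polymorphism.
- $N_e$ proxy $\pi_S/d_S$: diversity divided by a mutation-rate surrogate;
  comparable only within a comparison, which is exactly what the paired
  design needs. Undefined when $d_S = 0$.
- Gamma-DFE conversion: if deleterious fitness effects are gamma-distributed
  with shape $\beta$, then $\omega_1/\omega_2 = (N_1/N_2)^{-\beta}$, so an
  observed $\omega$ ratio implies $N_1/N_2 = (\omega_1/\omega_2)^{-1/\beta}$.
  The default $\beta = 0.5$ is a conservative upper value for empirical
  deleterious-DFE shapes; it is a user parameter of `analysis_config()`.

Undefined values propagate as explicit `NA` with per-comparison flags and
logged exclusion counts, so the n of every summary row is auditable
(`n_comparisons + n_excluded = subgroup size` is asserted in the tests).

# Paired inference

**Wilcoxon signed-rank.** Zero differences from the centre are dropped; tied
absolute differences get mid-ranks. For $m \le 20$ nonzero differences the
null distribution of the rank sum is computed exactly by a
generating-function convolution over the (doubled, hence integer) mid-ranks —
equivalent to enumerating all $2^m$ sign assignments, and verified against
explicit enumeration in the tests. Above $m = 20$ a normal approximation with
continuity and tie correction is used. The threshold matters because many
subgroup rows in this kind of dataset have $n \le 16$, where the normal
approximation is unreliable.

**Bootstrap.** Percentile interval of the mean over 1,000 resamples (BCa was
not chosen: the quantity is a mean of bounded values and the original
analysis used plain bootstrap percentiles). The seed is a required, logged
parameter; the caller's RNG stream is restored afterwards. Degenerate
percentile endpoints are reported as `NA` (the original tables print "∞" for
some CIs without defining the convention; `NA` is the honest equivalent).

**Tails.** One-tailed *less* for $\pi_S$ (the directional bottleneck
prediction), one-tailed *greater* for $\pi_N/(\pi_N+\pi_S)$ (the inefficient-
selection prediction), two-tailed for $\omega$ and $d_S$. The $N_e$-proxy
test is two-tailed because the source analysis does not state its tail; this
is recorded as a package decision. DoS is compared island-vs-mainland as a
signed-rank test on paired differences (DoS can be negative, so the
relative-value transform does not apply).

**Longest-alignment rule.** When one biological comparison has alignments
from several genomes, only the statistics of the longest alignment are used
(longer alignments have smaller sampling error). Rows of the manifest that
represent the same biological comparison share a `group_id`; ties are broken
mitochondrial > nuclear > chloroplast and logged. The genome tie-break order
is configurable and the default reflects the organellar dominance of typical
island–mainland sequence collections.

# The synthetic-data generator

`simulate_comparison()` draws a haploid structured-coalescent genealogy:
island and mainland demes of equal size, a mainland-to-island split
`split_time` (units of 2N generations) ago, an optional founder event in
which every island lineage surviving to the split picks one of
`bottleneck_founders` founders (same-founder lineages coalesce instantly),
and an outgroup that can only coalesce with the ingroup ancestor after
`outgroup_time`. Mutations are Poisson on branches at rate $\theta/2$ per
nucleotide site and are applied to explicit codon sequences (finite sites —
deliberately, so the NG86 pathway machinery is exercised on real multi-hit
codons). Selection is emulated by rejection:

- synonymous mutations: always accepted;
- stop-creating mutations: always rejected;
- non-synonymous mutations: neutral with probability
  `nonsyn_neutral_fraction` (accepted anywhere), *slightly deleterious* with
  probability `nonsyn_weak_fraction`, otherwise effectively lethal
  (rejected).

Slightly deleterious mutations are accepted only on genealogy edges whose
descendants are a proper subset of one deme's sample — i.e. they may
segregate but never fix. This is the minimal mechanism that gives the
generator the property the DoS statistic is designed to detect: pure
accept/reject applied uniformly would make the non-synonymous fractions of
polymorphism and divergence identical in expectation and DoS would centre on
zero even under strong purifying selection, which contradicts how
slightly-deleterious dynamics behave. With the weak class, DoS is negative
under purifying selection and zero under neutrality, and the tests verify
both directions.

**Defaults are a stated world, not knobs.** 250 codons (750 nt, the average
alignment length in the motivating dataset); 7 samples per species (its mean
chromosomes sampled); $\theta = 0.03$/site (the observed mitochondrial
$\pi_S$ scale, 0.027–0.039); split 20 and outgroup 40 × 2N generations, which
put island $\pi_S$ at ~5–6% of island+mainland $d_S$ (the observed regime);
non-synonymous fractions 0.2 neutral + 0.1 weak (reproducing
$\pi_N/(\pi_N+\pi_S) \approx 0.1\!-\!0.2$ and mildly negative DoS). The
"recent and extreme" bottleneck scenario used in the acceptance suite is 1
founder at split 0.005. Migration is exposed (`migration_rate`) but defaults
to 0, matching non-recombining organellar inheritance; there is no
recombination and no forward-time selection (non-goals).

**Calibration.** The generator's expected $\pi_S$ is computed analytically
per replicate from the root sequence: the linear coalescent value
$\theta_S$ (with the synonymous rate shrunk by stop-mutant rejection) times a
finite-sites factor $1/(1 + 4\theta/3)$, the Jukes–Cantor site saturation
integrated over the exponential pairwise coalescence time. The acceptance
suite checks the observed mean over 1,000 replicates against this expectation
within 3 Monte-Carlo standard errors, and checks that the one-tailed paired
test has type-I error within [0.03, 0.07] on neutral datasets (run at the
sanctioned scaled-down size of 500 datasets × 20 comparisons to fit the time
budget; 5+5 samples per comparison, legitimate because $\pi$ is sample-size
unbiased).

**What a green test does not establish.** The generator has no migration (by
default), no recombination, no selective sweeps or draft, no rate
heterogeneity among sites or lineages, equal deme sizes, and a star-free
three-taxon divergence topology. Green calibration tests establish that the
estimators recover the parameters of *this* world; they do not validate the
demographic realism of any particular empirical dataset.

# Numerical conventions

- Coordinates are 0-based half-open internally; all reported codon indices
  are 1-based.
- Codon computations run on integer codon indices against cached per-code
  lookup tables (sites, stop flags, 64×64 pathway-classified difference
  matrices); genetic codes themselves come from Biostrings (NCBI tables 1, 2,
  5, 11). Defaults per genome follow NCBI convention (vertebrate
  mitochondrial for mitochondrial, plastid for chloroplast, standard
  otherwise) and are overridable per manifest row — which code a given
  taxon/genome should use is a convention, not something the analysis can
  infer.
- $\omega$ with $d_S = 0$ is `NA` and flagged, never coerced to zero.
- All stochastic stages take explicit seeds; identical manifest + config +
  seed give byte-identical output files (asserted in the tests).
- The Fig.-2-style scatter uses island-branch + mainland-branch $d_S$ as
  "total divergence" (the between-clade quantity; the outgroup branch is
  deliberately excluded). The zero-diversity re-analysis drops comparisons
  with island $\pi_S = 0$ and recomputes the combined row.

# Known limitations

- Parsimony polarization underestimates changes on long branches (especially
  the outgroup branch at the default depth) and can misassign under
  homoplasy; it is a low-divergence method by construction.
- The segregating-change counts use a major-allele reference per codon
  column, which undercounts columns with three or more alleles on
  non-nested backgrounds; the diversity statistics do not share this
  limitation.
- No site-frequency-spectrum statistics, no DFE estimation from the SFS, no
  multiple-testing correction across subgroup rows, and no phylogenetic
  regression beyond the paired design — all deliberate scope boundaries.
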