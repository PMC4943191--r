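# selection_stats: selection-efficiency and adaptive-evolution statistics.

#' Non-synonymous fraction of diversity
#'
#' `pi_N / (pi_N + pi_S)`. Using total diversity as the denominator keeps the
#' statistic defined unless both diversities are zero (in which case the
#' comparison is uninformative and excluded downstream). Vectorised.
#'
#' @param pi_N,pi_S nonnegative diversities.
#' @return values in `[0, 1]`, `NA` where `pi_N + pi_S == 0`.
#' @export
pn_fraction <- function(pi_N, pi_S) {
  if (any(pi_N < 0, na.rm = TRUE) || any(pi_S < 0, na.rm = TRUE))
    stop("pn_fraction: negative input")
  out <- pi_N / (pi_N + pi_S)
  out[is.nan(out)] <- NA_real_
  out
}

#' Non-synonymous fraction of divergence
#'
#' `d_N / (d_N + d_S)`; `NA` where the sum is zero. Vectorised.
#'
#' @param d_N,d_S nonnegative divergences.
#' @return values in `[0, 1]` or `NA`.
#' @export
dn_fraction <- function(d_N, d_S) {
  if (any(d_N < 0, na.rm = TRUE) || any(d_S < 0, na.rm = TRUE))
    stop("dn_fraction: negative input")
  out <- d_N / (d_N + d_S)
  out[is.nan(out)] <- NA_real_
  out
}

#' Direction of selection statistic
#'
#' `DoS = d_N/(d_N+d_S) - pi_N/(pi_N+pi_S)`. Positive values indicate
#' evolutionary dynamics dominated by positive selection; negative values
#' indicate that slightly deleterious mutations predominate. Undefined
#' (`NA`, excluded downstream) when either fraction is undefined, i.e. the
#' statistic requires at least one substitution and one polymorphism.
#'
#' @param dN,dS,pi_N,pi_S nonnegative statistics (vectorised).
#' @return DoS values in `[-1, 1]` or `NA`.
#' @export
dos <- function(dN, dS, pi_N, pi_S) {
  dn_fraction(dN, dS) - pn_fraction(pi_N, pi_S)
}

#' Effective population size proxy
#'
#' `pi_S / d_S`, using synonymous divergence to approximate the mutation
#' rate. Comparable only within one island-mainland comparison (the proxy is
#' diversity divided by mutation rate times divergence time). `NA` where
#' `d_S` is 0.
#'
#' @param pi_S nonnegative synonymous diversity.
#' @param d_S synonymous divergence.
#' @return proxy values (>= 0) or `NA`.
#' @export
ne_proxy <- function(pi_S, d_S) {
  if (any(pi_S < 0, na.rm = TRUE) || any(d_S < 0, na.rm = TRUE))
    stop("ne_proxy: negative input")
  out <- pi_S / d_S
  out[!is.na(d_S) & d_S == 0] <- NA_real_
  out
}

#' Effective population size ratio implied by an omega ratio
#'
#' Under a gamma distribution of deleterious fitness effects with shape
#' `beta`, the omega values of two populations relate to their effective
#' population sizes as `omega1/omega2 = (N1/N2)^(-beta)`; solving for the
#' size ratio gives `N1/N2 = (omega1/omega2)^(-1/beta)`.
#'
#' @param omega_ratio positive ratio of omega values (population 1 over
#'   population 2).
#' @param beta gamma shape parameter (> 0). Default 0.5, a conservative
#'   upper value for the shape of the deleterious DFE.
#' @return the implied `N1/N2` (vectorised over `omega_ratio`).
#' @examples
#' ne_ratio_from_omega(1.33, 0.5)  # ~0.57
#' @export
ne_ratio_from_omega <- function(omega_ratio, beta = 0.5) {
  if (any(!is.finite(omega_ratio)) || any(omega_ratio <= 0))
    stop("omega_ratio must be positive and finite")
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("beta must be a single positive number")
  omega_ratio^(-1 / beta)
}

#' Per-side selection summary
#'
#' Combines polymorphism and divergence statistics of one lineage into the
#' selection-efficiency summary, with explicit `NA` for undefined values.
#'
#' @param pi_N,pi_S within-species diversities.
#' @param dN,dS lineage divergences.
#' @return list with `pn_fraction`, `dn_fraction`, `dos`, `ne_proxy` and
#'   logical `*_defined` flags.
#' @export
selection_summary <- function(pi_N, pi_S, dN, dS) {
  pnf <- pn_fraction(pi_N, pi_S)
  dnf <- dn_fraction(dN, dS)
  list(pn_fraction = pnf, dn_fraction = dnf,
       dos = dnf - pnf, ne_proxy = ne_proxy(pi_S, dS),
       pn_fraction_defined = !is.na(pnf),
       dn_fraction_defined = !is.na(dnf),
       dos_defined = !is.na(dnf - pnf),
       ne_proxy_defined = !is.na(ne_proxy(pi_S, dS)))
}
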