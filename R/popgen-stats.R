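# Per-locus diversity and neutrality statistics (the DnaSP subset used
# for the receptor loci): segregating sites, pi, Watterson's theta,
# Tajima's D and Fu & Li's D* (no outgroup), all under complete deletion
# of columns containing N or gaps.

# site summaries over included columns: distinct bases, minor counts
site_tables <- function(aln) {
  m <- included_mat(aln)
  if (ncol(m) == 0L)
    return(list(S = 0L, sites = integer(0), eta = 0L, eta_s = 0L,
                pi_total = 0, n = nrow(aln$mat), L_eff = 0L))
  n <- nrow(m)
  counts <- apply(m, 2, function(col) table(factor(col, levels = c("A", "C", "G", "T"))))
  k_distinct <- colSums(counts > 0L)
  var_cols <- which(k_distinct >= 2L)
  # mean pairwise differences (total, not per site)
  npairs <- n * (n - 1) / 2
  pi_total <- 0
  eta_s <- 0L
  eta <- 0L
  for (j in var_cols) {
    cj <- counts[, j]
    same <- sum(cj * (cj - 1) / 2)
    pi_total <- pi_total + (npairs - same) / npairs
    eta <- eta + (k_distinct[j] - 1L)
    eta_s <- eta_s + sum(cj == 1L)
  }
  sites <- which(aln$included)[var_cols]
  list(S = length(var_cols), sites = sites, eta = as.integer(eta),
       eta_s = as.integer(eta_s), pi_total = pi_total, n = n,
       L_eff = ncol(m))
}

#' Segregating sites
#'
#' Columns with at least two distinct bases among the alleles, after
#' complete deletion of columns containing N or gaps.
#'
#' @param aln `pop_alignment`
#' @return list with `S`, `sites` (1-based alignment columns) and
#'   `L_eff` (number of included columns)
#' @export
segregating_sites <- function(aln) {
  st <- site_tables(aln)
  list(S = st$S, sites = st$sites, L_eff = st$L_eff)
}

#' Nucleotide diversity (pi, per site)
#'
#' Average number of pairwise nucleotide differences per included site.
#'
#' @param aln `pop_alignment`
#' @return numeric scalar
#' @export
nucleotide_diversity <- function(aln) {
  if (nrow(aln$mat) < 2L) stop("need >= 2 alleles")
  st <- site_tables(aln)
  if (st$L_eff == 0L) return(0)
  st$pi_total / st$L_eff
}

harmonic <- function(k) if (k < 1L) 0 else sum(1 / seq_len(k))
harmonic2 <- function(k) if (k < 1L) 0 else sum(1 / seq_len(k)^2)

#' Watterson's theta (per site)
#'
#' `S / a1 / L_eff` with `a1 = sum(1/i, i = 1..n-1)`.
#'
#' @param aln `pop_alignment`
#' @return numeric scalar
#' @export
watterson_theta <- function(aln) {
  if (nrow(aln$mat) < 2L) stop("need >= 2 alleles")
  st <- site_tables(aln)
  if (st$L_eff == 0L || st$S == 0L) return(0)
  st$S / harmonic(st$n - 1L) / st$L_eff
}

# Tajima (1989) constants for sample size n
tajima_constants <- function(n) {
  a1 <- harmonic(n - 1L)
  a2 <- harmonic2(n - 1L)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# D from summary quantities (shared with the coalescent null)
tajima_d_from_summary <- function(n, S, pi_total) {
  k <- tajima_constants(n)
  (pi_total - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Tajima's D
#'
#' Standardized difference between the pairwise-difference and
#' segregating-site diversity estimators (Tajima 1989). Undefined when
#' there are no segregating sites (returns `NA` with a warning-free
#' `defined = FALSE` flag via [neutrality_test()]).
#'
#' @param aln `pop_alignment`
#' @return numeric scalar (`NA` when S = 0)
#' @export
tajimas_d <- function(aln) {
  st <- site_tables(aln)
  if (st$S == 0L) return(NA_real_)
  tajima_d_from_summary(st$n, st$S, st$pi_total)
}

# Fu & Li (1993) D* constants (corrected), sample size n
fu_li_dstar_constants <- function(n) {
  a <- harmonic(n - 1L)
  b <- harmonic2(n - 1L)
  cn <- 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * (a + 1 / n) - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * b + a^2 * dn -
           2 * (n * a * (a + 1)) / (n - 1)^2) / (a^2 + b)
  uD <- (n / (n - 1)) * (a - n / (n - 1)) - vD
  list(a = a, uD = uD, vD = vD)
}

fu_li_dstar_from_summary <- function(n, eta, eta_s) {
  k <- fu_li_dstar_constants(n)
  ((n / (n - 1)) * eta - k$a * eta_s) / sqrt(k$uD * eta + k$vD * eta^2)
}

#' Fu and Li's D* (no outgroup)
#'
#' Contrasts singleton mutations (variants observed in exactly one
#' allele) with the total number of mutations, using the corrected
#' constants of Fu & Li (1993). Undefined when there are no mutations.
#'
#' @param aln `pop_alignment`
#' @return numeric scalar (`NA` when there is no polymorphism)
#' @export
fu_li_dstar <- function(aln) {
  st <- site_tables(aln)
  if (st$eta == 0L) return(NA_real_)
  if (st$n < 3L) stop("Fu & Li's D* requires n >= 3")
  fu_li_dstar_from_summary(st$n, st$eta, st$eta_s)
}
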