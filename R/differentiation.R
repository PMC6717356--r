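# Per-SNP differentiation: SNP calling from allele alignments, coding
# effect annotation, Fisher's exact test on per-population allele counts
# with FDR adjustment, and mapping of significant nonsynonymous SNPs onto
# predicted transmembrane topology.

#' Call biallelic SNPs with per-population allele counts
#'
#' Variable included columns with exactly two bases become SNP records;
#' multi-allelic columns are skipped and listed in the `multiallelic`
#' attribute. `ref` is the overall major allele (alphabetical on ties).
#' The result carries attribute `fixed_difference`: whether any SNP is
#' fixed between the two populations (disjoint allele sets).
#'
#' @param aln `pop_alignment` with two populations; for `coding = TRUE`
#'   the alignment length must be a multiple of 3 (a complete ORF in
#'   frame 1)
#' @param coding annotate codon position and coding effect
#' @return data.frame: `locus, col, codon, codon_pos, ref, alt,
#'   ref_n1, alt_n1, ref_n2, alt_n2, pop1, pop2` and, when coding,
#'   `effect` (`synonymous`/`nonsynonymous`/`stop_gain`), `aa_ref`,
#'   `aa_alt`
#' @export
call_snps <- function(aln, coding = TRUE) {
  pops <- unique(aln$pop)
  if (length(pops) != 2L) stop("call_snps requires exactly two populations")
  if (coding && aln$L %% 3L != 0L)
    stop("coding alignment length is not a multiple of 3")
  m <- aln$mat
  cons <- apply(m, 2, function(col) {
    tb <- sort(table(col[!col %in% c("N", "-")]), decreasing = TRUE)
    if (length(tb) == 0L) "N" else names(tb)[1]
  })
  cds_cons <- paste(cons, collapse = "")
  i1 <- aln$pop == pops[1]
  rows <- list()
  multi <- integer(0)
  fixed_diff <- FALSE
  for (j in which(aln$included)) {
    col <- m[, j]
    tb <- table(col)
    if (length(tb) < 2L) next
    if (length(tb) > 2L) { multi <- c(multi, j); next }
    bases <- names(sort(tb, decreasing = TRUE))
    if (tb[bases[1]] == tb[bases[2]]) bases <- sort(bases)
    ref <- bases[1]; alt <- bases[2]
    b1 <- col[i1]; b2 <- col[!i1]
    if (length(intersect(unique(b1), unique(b2))) == 0L) fixed_diff <- TRUE
    row <- data.frame(
      locus = aln$locus, col = j,
      codon = if (coding) (j - 1L) %/% 3L + 1L else NA_integer_,
      codon_pos = if (coding) (j - 1L) %% 3L + 1L else NA_integer_,
      ref = ref, alt = alt,
      ref_n1 = sum(b1 == ref), alt_n1 = sum(b1 == alt),
      ref_n2 = sum(b2 == ref), alt_n2 = sum(b2 == alt),
      pop1 = pops[1], pop2 = pops[2], stringsAsFactors = FALSE)
    if (coding) {
      eff <- annotate_effect(list(col = j, ref = ref, alt = alt), cds_cons)
      row$effect <- eff$effect
      row$aa_ref <- eff$aa_ref
      row$aa_alt <- eff$aa_alt
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(locus = character(0), col = integer(0),
                         codon = integer(0), codon_pos = integer(0),
                         ref = character(0), alt = character(0),
                         ref_n1 = integer(0), alt_n1 = integer(0),
                         ref_n2 = integer(0), alt_n2 = integer(0),
                         pop1 = character(0), pop2 = character(0),
                         effect = character(0), aa_ref = character(0),
                         aa_alt = character(0), stringsAsFactors = FALSE)
  attr(out, "multiallelic") <- multi
  attr(out, "fixed_difference") <- fixed_diff
  out
}

#' Annotate the coding effect of a SNP
#'
#' Translates the reference and alternate codons (standard code) in the
#' context of the CDS; differing amino acids are nonsynonymous, and a
#' stop-gaining alternate allele is flagged `stop_gain`.
#'
#' @param snp list/row with `col` (1-based CDS position), `ref`, `alt`
#' @param cds in-frame reference CDS string (e.g. the alignment
#'   consensus)
#' @return list: `effect`, `aa_ref`, `aa_alt`
#' @export
annotate_effect <- function(snp, cds) {
  pos <- snp$col
  if (pos < 1L || pos > nchar(cds)) stop("SNP position outside the CDS")
  ci <- (pos - 1L) %/% 3L
  off <- (pos - 1L) %% 3L
  codon <- substr(cds, ci * 3L + 1L, ci * 3L + 3L)
  if (nchar(codon) < 3L) stop("SNP maps to an incomplete codon")
  ref_codon <- codon; substr(ref_codon, off + 1L, off + 1L) <- snp$ref
  alt_codon <- codon; substr(alt_codon, off + 1L, off + 1L) <- snp$alt
  aa_ref <- translate_dna(ref_codon)
  aa_alt <- translate_dna(alt_codon)
  effect <- if (aa_alt == "*" && aa_ref != "*") "stop_gain"
            else if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
  list(effect = effect, aa_ref = aa_ref, aa_alt = aa_alt)
}

#' Fisher's exact test for a 2x2 table (two-tailed)
#'
#' Exact hypergeometric enumeration with the point-probability rule: the
#' two-tailed p is the sum of probabilities of all tables (with the same
#' margins) whose point probability does not exceed the observed one
#' (within a relative tolerance of 1e-7).
#'
#' @param a,b,c,d cell counts (`a b / c d`), or `a` may be a 2x2 matrix
#' @return two-tailed p-value
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) { b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1] }
  if (any(c(a, b, c, d) < 0) || any(c(a, b, c, d) != round(c(a, b, c, d))))
    stop("cell counts must be non-negative integers")
  m <- a + c          # column 1 margin
  n2 <- b + d         # column 2 margin
  k <- a + b          # row 1 margin
  if (m + n2 == 0L) stop("empty table")
  lo <- max(0L, k - n2)
  hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Per-SNP differentiation tests
#'
#' Fisher's exact test on the per-population allele-count table of every
#' nonsynonymous SNP, with Benjamini-Hochberg adjustment either pooled
#' across all loci (default, `family = "pooled"`) or within each locus.
#' SNPs with adjusted p below `alpha` are flagged significant, and
#' per-locus counts of significant nonsynonymous SNPs are reported.
#'
#' @param snps SNP data.frame from [call_snps()] (one or more loci,
#'   `effect` column required)
#' @param alpha significance level after adjustment
#' @param family FDR family: `"pooled"` or `"per_locus"`
#' @return list: `snps` (input with `p_fisher`, `p_fdr`, `significant`
#'   added on nonsynonymous rows) and `per_locus` (locus, number of
#'   nonsynonymous SNPs, number significant)
#' @export
per_snp_differentiation <- function(snps, alpha = 0.05,
                                    family = c("pooled", "per_locus")) {
  family <- match.arg(family)
  if (!"effect" %in% names(snps)) stop("snps must carry an effect column")
  snps$p_fisher <- NA_real_
  snps$p_fdr <- NA_real_
  snps$significant <- NA
  ns <- which(snps$effect == "nonsynonymous")
  if (length(ns)) {
    snps$p_fisher[ns] <- vapply(ns, function(i)
      fisher_exact_2x2(snps$ref_n1[i], snps$ref_n2[i],
                       snps$alt_n1[i], snps$alt_n2[i]), numeric(1))
    if (family == "pooled") {
      snps$p_fdr[ns] <- fdr_adjust(snps$p_fisher[ns])
    } else {
      for (loc in unique(snps$locus[ns])) {
        ii <- ns[snps$locus[ns] == loc]
        snps$p_fdr[ii] <- fdr_adjust(snps$p_fisher[ii])
      }
    }
    snps$significant[ns] <- snps$p_fdr[ns] < alpha
  }
  loci <- unique(snps$locus)
  per_locus <- data.frame(
    locus = loci,
    n_nonsyn = vapply(loci, function(l)
      sum(snps$locus == l & snps$effect == "nonsynonymous"), integer(1)),
    n_significant = vapply(loci, function(l)
      sum(snps$locus == l & snps$effect == "nonsynonymous" &
            !is.na(snps$significant) & snps$significant), integer(1)),
    stringsAsFactors = FALSE)
  list(snps = snps, per_locus = per_locus)
}

#' Map a protein position onto transmembrane topology
#'
#' Positions inside the k-th helix span are labelled `TMk`. With seven
#' helices, the flanking segments follow the GPCR convention
#' (extracellular N-terminus): `N-term`, then `ICL1, ECL1, ICL2, ECL2,
#' ICL3, ECL3` alternating after each helix, then `C-term`. With any
#' other helix count, the stand-in labels `outside`/`TM`/`inside` are
#' used, alternating from an outside N-terminus.
#'
#' @param aa_pos 1-based protein position (e.g. the SNP's codon index)
#' @param tm result of [predict_tm_helices()] or
#'   [parse_topology_string()] (list with `count`, `spans`)
#' @param protein_length total protein length
#' @return domain label
#' @export
map_snp_to_topology <- function(aa_pos, tm, protein_length) {
  if (aa_pos < 1L || aa_pos > protein_length)
    stop("position beyond the protein")
  sp <- tm$spans
  k <- nrow(sp)
  seven <- k == 7L
  if (k == 0L) return(if (seven) "N-term" else "outside")
  inside_tm <- which(sp$start <= aa_pos & aa_pos <= sp$end)
  if (length(inside_tm)) return(paste0("TM", inside_tm[1]))
  n_before <- sum(sp$end < aa_pos)
  if (seven) {
    if (n_before == 0L) return("N-term")
    if (n_before == 7L) return("C-term")
    if (n_before %% 2L == 1L) return(paste0("ICL", (n_before + 1L) / 2L))
    return(paste0("ECL", n_before / 2L))
  }
  if (n_before %% 2L == 0L) "outside" else "inside"
}
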