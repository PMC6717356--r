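# Between-population differentiation: Hudson's FST (1 - Hw/Hb) and the
# Snn nearest-neighbour permutation test (Hudson 2000).

#' Hudson's FST between two populations
#'
#' `FST = 1 - Hw/Hb` where `Hw` is the mean within-population pairwise
#' difference count (the two populations weighted equally) and `Hb` the
#' mean between-population pairwise difference count, over included
#' columns. Undefined (`fst_defined = FALSE`) when the locus has no
#' polymorphism.
#'
#' @param aln `pop_alignment` with exactly two populations
#' @return list: `fst`, `fst_defined`, `Hw`, `Hb`
#' @export
hudson_fst <- function(aln) {
  pops <- unique(aln$pop)
  if (length(pops) != 2L) stop("hudson_fst requires exactly two populations")
  if (any(table(aln$pop) < 2L)) stop("both populations need >= 2 alleles")
  st <- site_tables(aln)
  if (st$S == 0L)
    return(list(fst = NA_real_, fst_defined = FALSE, Hw = 0, Hb = 0))
  d <- pairwise_diffs(aln)
  i1 <- which(aln$pop == pops[1])
  i2 <- which(aln$pop == pops[2])
  hw1 <- mean(d[i1, i1][upper.tri(d[i1, i1])])
  hw2 <- mean(d[i2, i2][upper.tri(d[i2, i2])])
  Hw <- (hw1 + hw2) / 2
  Hb <- mean(d[i1, i2])
  if (Hb == 0)
    return(list(fst = NA_real_, fst_defined = FALSE, Hw = Hw, Hb = Hb))
  list(fst = 1 - Hw / Hb, fst_defined = TRUE, Hw = Hw, Hb = Hb)
}

# per-sequence nearest-neighbour same-population fraction, given a
# distance matrix and labels; ties at the minimum distance are split
# fractionally
snn_statistic <- function(d, labels) {
  n <- nrow(d)
  x <- numeric(n)
  for (i in seq_len(n)) {
    di <- d[i, -i]
    lab <- labels[-i]
    nn <- which(di == min(di))
    x[i] <- sum(lab[nn] == labels[i]) / length(nn)
  }
  mean(x)
}

#' Hudson's Snn nearest-neighbour test
#'
#' The statistic is the average, over sequences, of the fraction of each
#' sequence's nearest neighbours (minimum pairwise distance; ties split
#' fractionally) that belong to its own population. Significance is by
#' label permutation preserving population sizes; the permutation p-value
#' is one-tailed (large Snn = differentiation) and computed as
#' `(1 + #{perm >= observed}) / (reps + 1)`.
#'
#' @param aln `pop_alignment` with two populations
#' @param reps number of label permutations
#' @param seed optional integer seed
#' @return list: `snn`, `p`, `reps`, `seed`
#' @export
snn_test <- function(aln, reps = 10000L, seed = 1L) {
  pops <- unique(aln$pop)
  if (length(pops) != 2L) stop("snn_test requires exactly two populations")
  d <- pairwise_diffs(aln)
  labels <- aln$pop
  obs <- snn_statistic(d, labels)
  # precompute nearest-neighbour index sets: permutation only relabels
  n <- nrow(d)
  nn_sets <- lapply(seq_len(n), function(i) {
    di <- d[i, -i]
    idx <- seq_len(n)[-i]
    idx[di == min(di)]
  })
  snn_of <- function(lab) {
    mean(vapply(seq_len(n), function(i)
      sum(lab[nn_sets[[i]]] == lab[i]) / length(nn_sets[[i]]), numeric(1)))
  }
  count <- with_seed(seed, {
    cnt <- 0L
    for (r in seq_len(reps)) {
      if (snn_of(sample(labels)) >= obs - 1e-12) cnt <- cnt + 1L
    }
    cnt
  })
  list(snn = obs, p = (1 + count) / (reps + 1), reps = reps, seed = seed)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: `p_adj(i) = min_{j: p_(j) >= p_(i)} min(1, m *
#' p_(j) / j)`; monotone in the input p-values, capped at 1, returned in
#' the input order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]` (`NA` passed
#'   through)
#' @return adjusted p-values, same order
#' @export
fdr_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  p <- pvals[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  out <- rep(NA_real_, length(pvals))
  if (m > 0L) {
    o <- order(p, decreasing = TRUE)
    adj <- pmin(1, m / seq(m, 1) * p[o])
    adj <- cummin(adj)
    res <- numeric(m)
    res[o] <- adj
    out[ok] <- res
  }
  out
}
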