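# Synthetic inputs for the comparative and population-genetic stages:
# Brownian-motion traits on a dated tree, and two-population coalescent
# alignments under a clean-split (no migration) model with infinite-sites
# mutation.

#' Simulate Brownian-motion traits on a tree
#'
#' A trait evolves from the root value 0 with independent Normal
#' increments of variance `sigma2 * branch length`. An optional additive
#' `lifestyle_effect * code` shift on the tips creates a true association
#' with a binary lifestyle code.
#'
#' @param tree `phylo` with branch lengths
#' @param sigma2 Brownian rate (variance per unit branch length)
#' @param seed optional integer seed
#' @param lifestyle named 0/1 vector over tips (required when
#'   `lifestyle_effect != 0`)
#' @param lifestyle_effect additive tip shift per unit of lifestyle code
#' @return named numeric vector of tip values
#' @export
simulate_bm_traits <- function(tree, sigma2, seed = NULL, lifestyle = NULL,
                               lifestyle_effect = 0) {
  stopifnot(inherits(tree, "phylo"), sigma2 >= 0)
  ntip <- length(tree$tip.label)
  with_seed(seed, {
    nn <- ntip + tree$Nnode
    x <- numeric(nn)
    root <- ntip + 1L
    # preorder: parents appear before children in reorder(tree)
    tr <- stats::reorder(tree, "cladewise")
    for (i in seq_len(nrow(tr$edge))) {
      par <- tr$edge[i, 1]; ch <- tr$edge[i, 2]
      x[ch] <- x[par] + stats::rnorm(1, 0, sqrt(sigma2 * tr$edge.length[i]))
    }
    out <- setNames(x[seq_len(ntip)], tree$tip.label)
    if (lifestyle_effect != 0) {
      if (is.null(lifestyle) || !all(tree$tip.label %in% names(lifestyle)))
        stop("lifestyle codes required for a lifestyle effect")
      out <- out + lifestyle_effect * unname(lifestyle[tree$tip.label])
    }
    out
  })
}

#' Simulate a two-population alignment under a split model
#'
#' Structured coalescent for `n1 + n2` alleles in two equal-sized
#' populations that merged `split_time` coalescent units (of 2N
#' generations) ago, with no migration; `split_time = 0` is panmixia.
#' Mutations are Poisson with rate `theta/2` per lineage per unit time
#' (so a panmictic locus has `E[S] = theta * a1`), each hitting a
#' distinct column of a random ancestral sequence (infinite sites).
#'
#' @param n1,n2 alleles per population (>= 2)
#' @param L alignment length (nt)
#' @param theta population-scaled mutation rate per locus (4 N mu)
#' @param split_time population split time, coalescent units (0 =
#'   panmixia)
#' @param seed optional integer seed
#' @param pop_names labels for the two populations
#' @param locus locus id
#' @return [pop_alignment()]; attribute `truth` records the parameters
#'   and realized mutation count
#' @export
simulate_two_pop <- function(n1, n2, L = 1000L, theta = 5, split_time = 0,
                             seed = NULL, pop_names = c("pop1", "pop2"),
                             locus = "locus") {
  stopifnot(n1 >= 2L, n2 >= 2L, L >= 1L, split_time >= 0)
  if (theta <= 0) stop("theta must be positive")
  with_seed(seed, {
    n <- n1 + n2
    # active lineages: list of tip-index sets; deme of each lineage
    sets <- lapply(seq_len(n), identity)
    deme <- c(rep(1L, n1), rep(2L, n2))
    branch_sets <- list()
    branch_len <- numeric(0)
    # per-lineage accumulated branch length since the lineage arose
    open_len <- numeric(n)
    t_now <- 0
    merge_pair <- function(i, j) {
      # close two lineages into branches, open their ancestor
      branch_sets[c(length(branch_sets) + 1L, length(branch_sets) + 2L)] <<-
        list(sets[[i]], sets[[j]])
      branch_len <<- c(branch_len, open_len[i], open_len[j])
      new_set <- c(sets[[i]], sets[[j]])
      keep <- setdiff(seq_along(sets), c(i, j))
      sets <<- c(sets[keep], list(new_set))
      deme <<- c(deme[keep], deme[i])
      open_len <<- c(open_len[keep], 0)
    }
    # phase 1: separate demes until split_time
    repeat {
      k1 <- sum(deme == 1L); k2 <- sum(deme == 2L)
      r1 <- k1 * (k1 - 1) / 2; r2 <- k2 * (k2 - 1) / 2
      rate <- r1 + r2
      if (rate == 0 || t_now >= split_time) break
      dt <- stats::rexp(1, rate)
      if (t_now + dt >= split_time) {
        open_len <- open_len + (split_time - t_now)
        t_now <- split_time
        break
      }
      open_len <- open_len + dt
      t_now <- t_now + dt
      in_deme <- if (stats::runif(1) < r1 / rate) which(deme == 1L)
                 else which(deme == 2L)
      pair <- sample(in_deme, 2L)
      merge_pair(pair[1], pair[2])
    }
    # lineages that ran out of coalescence partners still wait (and
    # accrue branch length) until the split
    if (t_now < split_time && length(sets) > 1L)
      open_len <- open_len + (split_time - t_now)
    # phase 2: merged ancestral population
    deme[] <- 1L
    while (length(sets) > 1L) {
      k <- length(sets)
      dt <- stats::rexp(1, k * (k - 1) / 2)
      open_len <- open_len + dt
      pair <- if (k == 2L) c(1L, 2L) else sample.int(k, 2L)
      merge_pair(pair[1], pair[2])
    }
    # drop zero-length branches (cannot carry mutations)
    keep <- branch_len > 0
    branch_sets <- branch_sets[keep]
    branch_len <- branch_len[keep]
    total_len <- sum(branch_len)
    n_mut <- stats::rpois(1, theta / 2 * total_len)
    if (n_mut > L)
      stop("more mutations (", n_mut, ") than sites (", L,
           "); increase L or decrease theta")
    anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    mat <- matrix(rep(anc, each = n), nrow = n)
    if (n_mut > 0L) {
      cols <- sample.int(L, n_mut)
      br <- sample.int(length(branch_len), n_mut, replace = TRUE,
                       prob = branch_len)
      for (m in seq_len(n_mut)) {
        j <- cols[m]
        derived <- sample(setdiff(c("A", "C", "G", "T"), anc[j]), 1L)
        mat[branch_sets[[br[m]]], j] <- derived
      }
    }
    seqs <- apply(mat, 1, paste, collapse = "")
    names(seqs) <- sprintf("allele%02d", seq_len(n))
    aln <- pop_alignment(seqs, rep(pop_names, c(n1, n2)), locus)
    attr(aln, "truth") <- list(n1 = n1, n2 = n2, L = L, theta = theta,
                               split_time = split_time, n_mutations = n_mut)
    aln
  })
}
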