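# Coalescent significance for the neutrality tests: the null distribution
# of D / D* is built from standard neutral coalescent genealogies for n
# alleles conditioned on the observed number of segregating sites
# (mutations dropped uniformly on the total branch length), mirroring the
# "10,000 replicates of coalescent simulation" workflow.

# Evaluate `code` under a temporary RNG state seeded with `seed`
# (restores the caller's .Random.seed afterwards).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# One neutral coalescent genealogy for n tips: returns branch lengths and
# the number of descendant tips per branch (root branch excluded).
coalescent_branches <- function(n) {
  nb <- 2L * n - 2L  # all branches below the root
  desc <- integer(nb + 1L)
  blen <- numeric(nb + 1L)
  desc[1:n] <- 1L
  active <- 1:n
  nxt <- n + 1L
  for (k in n:2) {
    t <- rexp(1, rate = k * (k - 1) / 2)
    blen[active] <- blen[active] + t
    pair <- if (k == 2L) active else sample(active, 2L)
    desc[nxt] <- desc[pair[1]] + desc[pair[2]]
    active <- c(setdiff(active, pair), nxt)
    nxt <- nxt + 1L
  }
  list(blen = blen[1:nb], desc = desc[1:nb])
}

#' Simulate the null distribution of D and D* given n and S
#'
#' For each replicate a neutral genealogy is drawn, `S` mutations are
#' placed multinomially on branches proportionally to branch length
#' (infinite sites), and Tajima's D and Fu & Li's D* are computed from
#' the resulting site-frequency spectrum.
#'
#' @param n number of alleles
#' @param S observed segregating sites (conditioning value)
#' @param reps replicates
#' @param seed optional integer seed (RNG state is restored)
#' @return data.frame with columns `D` and `Dstar`
#' @export
coalescent_null <- function(n, S, reps = 10000L, seed = NULL) {
  stopifnot(n >= 3L, S >= 1L, reps >= 1L)
  with_seed(seed, {
    D <- numeric(reps)
    Ds <- numeric(reps)
    for (r in seq_len(reps)) {
      g <- coalescent_branches(n)
      mut <- drop(stats::rmultinom(1L, S, prob = g$blen))
      f <- g$desc[mut > 0L]
      m <- mut[mut > 0L]
      npairs <- n * (n - 1) / 2
      pi_total <- sum(m * f * (n - f)) / npairs
      eta_s <- sum(m[f == 1L | f == (n - 1L)])
      D[r] <- tajima_d_from_summary(n, S, pi_total)
      Ds[r] <- fu_li_dstar_from_summary(n, S, eta_s)
    }
    data.frame(D = D, Dstar = Ds)
  })
}

# two-tailed empirical p from a simulated null
empirical_p_two_tailed <- function(obs, sims) {
  lo <- mean(sims <= obs)
  hi <- mean(sims >= obs)
  min(1, 2 * min(lo, hi))
}

#' Coalescent p-value for an observed statistic
#'
#' @param obs observed statistic value
#' @param n,S sample size and segregating sites to condition on
#' @param statistic `"D"` (Tajima) or `"Dstar"` (Fu & Li)
#' @param reps replicates (>= 1000 recommended)
#' @param seed optional seed
#' @return two-tailed empirical p: `2 * min(P(sim <= obs), P(sim >= obs))`
#'   capped at 1
#' @export
coalescent_pvalue <- function(obs, n, S, statistic = c("D", "Dstar"),
                              reps = 10000L, seed = NULL) {
  statistic <- match.arg(statistic)
  if (S < 1L) stop("p undefined when S = 0")
  if (is.na(obs)) return(NA_real_)
  sims <- coalescent_null(n, S, reps, seed)[[statistic]]
  empirical_p_two_tailed(obs, sims)
}

#' Neutrality tests for one locus
#'
#' Computes Tajima's D and Fu & Li's D* and their two-tailed coalescent
#' p-values from a single shared set of simulated genealogies
#' (conditioned on the observed S).
#'
#' @param aln `pop_alignment`
#' @param reps coalescent replicates
#' @param seed integer seed (logged in the result)
#' @return list: `tajima_d`, `fu_li_dstar`, `p_tajima`, `p_fuli`, `S`,
#'   `n`, `reps`, `seed`, `defined`
#' @export
neutrality_test <- function(aln, reps = 10000L, seed = 1L) {
  st <- site_tables(aln)
  if (st$S == 0L)
    return(list(tajima_d = NA_real_, fu_li_dstar = NA_real_,
                p_tajima = NA_real_, p_fuli = NA_real_, S = 0L, n = st$n,
                reps = reps, seed = seed, defined = FALSE))
  d <- tajimas_d(aln)
  ds <- fu_li_dstar(aln)
  sims <- coalescent_null(st$n, st$S, reps, seed)
  list(tajima_d = d, fu_li_dstar = ds,
       p_tajima = empirical_p_two_tailed(d, sims$D),
       p_fuli = empirical_p_two_tailed(ds, sims$Dstar),
       S = st$S, n = st$n, reps = reps, seed = seed, defined = TRUE)
}
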