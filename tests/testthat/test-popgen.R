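# Diversity and neutrality statistics against hand arithmetic, the
# frozen independent-implementation values, and brute-force oracles;
# coalescent significance; FST and Snn; BH adjustment.

test_that("segregating sites and complete deletion", {
  a <- pop_alignment(c(x1 = "ACGT", x2 = "ACGT", x3 = "ACGT", x4 = "ACGT"),
                     rep("p", 4))
  expect_equal(segregating_sites(a)$S, 0L)
  b <- pop_alignment(c(x1 = "AACT", x2 = "AACT", x3 = "GACT", x4 = "GACT"),
                     rep("p", 4))
  expect_equal(segregating_sites(b)$S, 1L)
  expect_equal(segregating_sites(b)$sites, 1L)
  # N column dropped from both S and L_eff
  cc <- pop_alignment(c(x1 = "AACT", x2 = "NACT", x3 = "GACT", x4 = "GACT"),
                      rep("p", 4))
  st <- segregating_sites(cc)
  expect_equal(st$S, 0L)
  expect_equal(st$L_eff, 3L)
  expect_equal(st$S, s_oracle(c("AACT", "NACT", "GACT", "GACT")))
})

test_that("pi and theta match hand arithmetic and brute force", {
  two <- pop_alignment(c(a1 = paste0("A", strrep("C", 99)),
                         a2 = paste0("G", strrep("C", 99))), c("p", "p"))
  expect_equal(nucleotide_diversity(two), 0.01)
  expect_equal(watterson_theta(two), 0.01)  # n=2: a1 = 1
  same <- pop_alignment(c(a1 = "ACGTACGT", a2 = "ACGTACGT"), c("p", "p"))
  expect_equal(nucleotide_diversity(same), 0)
  expect_equal(watterson_theta(same), 0)
  # n=4, S=11, L=1000: theta = 11 / (11/6) / 1000 = 0.006
  set.seed(12)
  base <- strsplit(rand_dna(1000), "")[[1]]
  mat <- matrix(rep(base, each = 4), nrow = 4)
  flip <- c(A = "G", C = "T", G = "A", T = "C")
  cols <- sample(1000, 11)
  for (j in cols[1:8]) mat[sample(4, 1), j] <- flip[[mat[1, j]]]
  for (j in cols[9:11]) mat[sample(4, 2), j] <- flip[[mat[1, j]]]
  a4 <- aln_from_mat(mat, rep("p", 4))
  expect_equal(watterson_theta(a4), 11 / (11 / 6) / 1000, tolerance = 1e-12)
  expect_equal(nucleotide_diversity(a4), pi_oracle(apply(mat, 1, paste,
                                                         collapse = "")))
  # random small alignments vs brute-force oracles
  for (rep in 1:10) {
    m <- matrix(sample(c("A", "C", "G", "T", "N"), 6 * 30, TRUE,
                       prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), nrow = 6)
    seqs <- apply(m, 1, paste, collapse = "")
    if (all(apply(m, 2, function(x) any(x == "N")))) next
    al <- pop_alignment(setNames(seqs, paste0("s", 1:6)), rep("p", 6))
    expect_equal(nucleotide_diversity(al), pi_oracle(seqs))
    expect_equal(segregating_sites(al)$S, s_oracle(seqs))
  }
})

test_that("Tajima's D: zero case, sign law, frozen oracle value", {
  # n=4 with 8 singleton + 3 two-two columns: pi_total = S/a1 -> D = 0
  base <- strsplit(strrep("A", 400), "")[[1]]
  mat <- matrix(rep(base, each = 4), nrow = 4)
  for (j in 1:8) mat[1 + (j %% 4), j] <- "G"
  for (j in 9:11) mat[c(1, 2), 50 + j] <- "G"
  a <- aln_from_mat(mat, rep("p", 4))
  expect_equal(tajimas_d(a), 0, tolerance = 1e-12)
  # all singletons -> negative D; frozen toy value
  sing <- matrix(rep(strsplit(strrep("T", 200), "")[[1]], each = 6), nrow = 6)
  for (j in 1:10) sing[1 + (j %% 6), j * 3] <- "A"
  expect_lt(tajimas_d(aln_from_mat(sing, rep("p", 6))), 0)
  expect_equal(tajimas_d(toy10_aln()), -0.6693125510, tolerance = 1e-6)
  expect_equal(nucleotide_diversity(toy10_aln()), 0.0444444444, tolerance = 1e-7)
  expect_equal(watterson_theta(toy10_aln()), 0.0530228644, tolerance = 1e-7)
  expect_equal(segregating_sites(toy10_aln())$S, 6L)
  # undefined at S = 0
  mono <- pop_alignment(c(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAA"),
                        rep("p", 4))
  expect_true(is.na(tajimas_d(mono)))
  # sign(D) == sign(pi_total - S/a1) on random simulated loci
  for (i in 1:20) {
    al <- simulate_two_pop(4, 4, L = 300, theta = 3, seed = 500 + i)
    st <- v1rpipe:::site_tables(al)
    if (st$S == 0) next
    lhs <- sign(tajimas_d(al))
    rhs <- sign(st$pi_total - st$S / v1rpipe:::harmonic(st$n - 1))
    expect_true(lhs == rhs || (lhs == 0 && rhs == 0))
  }
})

test_that("Fu & Li's D*: sign structure and frozen oracle values", {
  # S > 0 with no singletons -> positive; all singletons -> negative
  base <- strsplit(strrep("C", 300), "")[[1]]
  m <- matrix(rep(base, each = 8), nrow = 8)
  for (j in 1:6) m[1:4, j * 7] <- "T"   # intermediate-frequency variants
  expect_gt(fu_li_dstar(aln_from_mat(m, rep("p", 8))), 0)
  m2 <- matrix(rep(base, each = 8), nrow = 8)
  for (j in 1:6) m2[1 + (j %% 8), j * 7] <- "T"
  expect_lt(fu_li_dstar(aln_from_mat(m2, rep("p", 8))), 0)
  expect_equal(fu_li_dstar(toy5_aln()), -0.4101746497, tolerance = 1e-6)
  expect_equal(fu_li_dstar(toy10_aln()), -0.3675456610, tolerance = 1e-6)
})

test_that("coalescent p-values behave like empirical two-tailed tests", {
  nul <- coalescent_null(10, 5, reps = 2000, seed = 77)
  expect_equal(names(nul), c("D", "Dstar"))
  med <- median(nul$D)
  p_med <- coalescent_pvalue(med, 10, 5, "D", reps = 2000, seed = 77)
  expect_gt(p_med, 0.9)
  p_far <- coalescent_pvalue(-10, 10, 5, "D", reps = 2000, seed = 77)
  expect_lte(p_far, 2 / 2000)
  # same seed -> identical distribution; RNG state is restored
  before <- runif(1)
  nul2 <- coalescent_null(10, 5, reps = 200, seed = 3)
  nul3 <- coalescent_null(10, 5, reps = 200, seed = 3)
  expect_identical(nul2, nul3)
  expect_error(coalescent_pvalue(0.5, 10, 0, "D"), "undefined")
  # neutrality_test ties it together
  nt <- neutrality_test(toy10_aln(), reps = 1000, seed = 5)
  expect_equal(nt$S, 6L)
  expect_true(nt$defined)
  expect_true(nt$p_tajima > 0 && nt$p_tajima <= 1)
  expect_true(nt$p_fuli > 0 && nt$p_fuli <= 1)
  mono <- pop_alignment(c(a = "AAAA", b = "AAAA", c = "AAAA"), rep("p", 3))
  expect_false(neutrality_test(mono, reps = 10)$defined)
})

test_that("Hudson's FST: fixed difference, undefined case, symmetry", {
  fixed <- pop_alignment(
    c(a1 = "AAAAAA", a2 = "AAAAAA", b1 = "TTTTTT", b2 = "TTTTTT"),
    c("p1", "p1", "p2", "p2"))
  f <- hudson_fst(fixed)
  expect_true(f$fst_defined)
  expect_equal(f$fst, 1)
  mono <- pop_alignment(c(a1 = "AAaa", a2 = "AAAA", b1 = "AAAA",
                          b2 = "AAAA"), c("p1", "p1", "p2", "p2"))
  expect_false(hudson_fst(mono)$fst_defined)  # the monomorphic-locus case
  # swapping population labels leaves FST unchanged
  sw <- simulate_two_pop(5, 7, L = 600, theta = 6, split_time = 1, seed = 88)
  f1 <- hudson_fst(sw)
  swapped <- pop_alignment(apply(sw$mat, 1, paste, collapse = ""),
                           ifelse(sw$pop == "pop1", "pop2", "pop1"))
  expect_equal(hudson_fst(swapped)$fst, f1$fst)
})

test_that("Snn: hand-computable toys, bounds, relabelling invariance", {
  sep <- pop_alignment(c(x1 = "AAAA", x2 = "AAAT", x3 = "AAAA",
                         y1 = "TTTA", y2 = "TTTT", y3 = "TTTT"),
                       rep(c("p1", "p2"), each = 3))
  s <- snn_test(sep, reps = 99, seed = 1)
  expect_equal(s$snn, 1)
  # mixed toy, verified against the independent definition-level oracle
  seqs <- c(a = "AACC", b = "AACT", c = "ATCC", d = "TTGG", e = "TTGA",
            f = "AACC")
  pops <- c("p1", "p1", "p1", "p2", "p2", "p2")
  mixed <- pop_alignment(seqs, pops)
  sm <- snn_test(mixed, reps = 99, seed = 2)
  expect_equal(sm$snn, snn_oracle(unname(seqs), pops))
  expect_true(sm$snn >= 0 && sm$snn <= 1)
  expect_true(sm$p > 0 && sm$p <= 1)
  # reordering sequences within populations does not change Snn
  perm <- c(2, 1, 3, 5, 6, 4)
  reord <- pop_alignment(seqs[perm], pops[perm])
  expect_equal(snn_test(reord, reps = 9, seed = 3)$snn, sm$snn)
})

test_that("BH adjustment: hand cases and p.adjust agreement", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.37), 0.37)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  set.seed(14)
  for (rep in 1:10) {
    p <- runif(sample(3:40, 1))
    expect_equal(fdr_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(fdr_adjust(p) >= p))  # never decreases
  }
  # NA pass-through keeps positions
  p2 <- c(0.01, NA, 0.04)
  a2 <- fdr_adjust(p2)
  expect_true(is.na(a2[2]))
  expect_equal(a2[c(1, 3)], p.adjust(c(0.01, 0.04), "BH"))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("Mann-Whitney U matches wilcox.test in both regimes", {
  set.seed(9)
  x <- rnorm(8); y <- rnorm(9) + 0.5
  mine <- mann_whitney_u(x, y)
  ref <- wilcox.test(x, y, exact = TRUE)
  expect_equal(mine$U, unname(ref$statistic))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  xl <- rnorm(15); yl <- c(rnorm(14), xl[1])  # tie forces approximation
  mine2 <- mann_whitney_u(xl, yl)
  ref2 <- suppressWarnings(wilcox.test(xl, yl, exact = FALSE,
                                       correct = FALSE))
  expect_equal(mine2$p, ref2$p.value, tolerance = 1e-9)
})
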