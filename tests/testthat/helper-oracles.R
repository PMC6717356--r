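# Independent oracles and small fixture builders shared across tests.

# brute-force Smith-Waterman (Gotoh affine gaps), scores only
sw_oracle <- function(q, s, open = 11, ext = 1) {
  mat <- v1rpipe:::blosum62()
  qa <- strsplit(q, "")[[1]]
  sa <- strsplit(s, "")[[1]]
  n <- length(qa); m <- length(sa)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(E[i, j - 1] - ext, H[i, j - 1] - open - ext)
      F[i, j] <- max(F[i - 1, j] - ext, H[i - 1, j] - open - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[qa[i - 1], sa[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# brute-force pi (per site) over all allele pairs, complete deletion
pi_oracle <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  keep <- apply(mat, 2, function(cc) !any(cc %in% c("N", "-")))
  mat <- mat[, keep, drop = FALSE]
  n <- nrow(mat)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(mat[i, ] != mat[j, ])
  tot / choose(n, 2) / ncol(mat)
}

# brute-force segregating-site count, complete deletion
s_oracle <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  keep <- apply(mat, 2, function(cc) !any(cc %in% c("N", "-")))
  sum(apply(mat[, keep, drop = FALSE], 2,
            function(cc) length(unique(cc)) > 1))
}

# independent Snn computation straight from the definition
snn_oracle <- function(seqs, pops) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(mat)
  d <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- sum(mat[i, ] != mat[j, ])
  mean(vapply(1:n, function(i) {
    di <- d[i, -i]
    lab <- pops[-i]
    nn <- which(di == min(di))
    sum(lab[nn] == pops[i]) / length(nn)
  }, numeric(1)))
}

# fixed toy alignment frozen against an independent dendropy/popgenstat
# computation: S = 6, pi = 0.04444444, theta_w = 0.05302286,
# Tajima D = -0.6693126; eta_s = 3, Fu & Li D* = -0.3675457
toy10 <- c(
  s0 = "ATGGCTACGTTACGATCCGATTGCAAGGCTTAGACCGTAA",
  s1 = "ATGGCTACGTTACGATCCGATTGCAAGGCTTAGACCGTAA",
  s2 = "ATGGCTACGTTACGATCAGATTGCAAGGCTTAGACCGTAA",
  s3 = "ATGGCTACGTTACGATCAGATTGCAAGGCCTAGACCGTAA",
  s4 = "ATGGCTACGTTGCGATCCGATTGCAAGGCTTAGACCGTAA",
  s5 = "ATGGCTACGTTGCGATCCGATTGCAAGGCTTAGACCGTAA",
  s6 = "ATAGCTACGTTACGATCCGATTGCAAGGCTTAGACCGTAA",
  s7 = "ATGGCTACGTTACGATCCGATTGCAAGGCTTAGACCGTAA",
  s8 = "ATGGCTACGTTACGATCCGATTGTAAGGCTTAGACCGTAA",
  s9 = "ATGGCTACGTTACGATCAGATTGCAAGGCCTAGACCGTGA")

toy10_aln <- function() pop_alignment(toy10, rep(c("a", "b"), each = 5))

# n = 5 toy: eta = 4, eta_s = 3, D* = -0.4101746 (independent formula
# transcription in Python, frozen)
toy5 <- c(
  t0 = "ACGTACGTACGTACGTACGTACGTACGTAC",
  t1 = "ACGAACGTACGTACGTACGTACGTACGTAC",
  t2 = "ACGAACGTACCTACGTACGTACGTACGTAC",
  t3 = "ACGTACGTACGTACGTACGTTCGTACGTAC",
  t4 = "ACGTACGTACGTACGTACGTACGTAGGTAC")

toy5_aln <- function() pop_alignment(toy5, c("a", "a", "a", "b", "b"))

# random DNA string from the current RNG
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# build a pop_alignment from a matrix of characters
aln_from_mat <- function(mat, pops, locus = "toy") {
  pop_alignment(apply(mat, 1, paste, collapse = ""), pops, locus)
}

# tiny config with cheap Monte-Carlo settings for pipeline tests
test_config <- function(...) {
  default_config(coalescent_reps = 500L, permutation_reps = 199L, ...)
}
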