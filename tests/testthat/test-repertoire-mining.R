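# Mining operations: translation, search, filtering, merging, ORF
# extension, TM prediction, classification, identity confirmation.

test_that("six-frame translation follows the standard code", {
  fr <- six_frame_translate("ATGAAATAA")
  expect_equal(fr$F0, "MK*")
  fr2 <- six_frame_translate("ATG")
  expect_equal(unname(unlist(fr2[c("F0", "F1", "F2")])), c("M", "", ""))
  # reverse-complement frame: revcomp("TTACATCAT") = "ATGATGTAA"
  expect_equal(six_frame_translate("TTACATCAT")$R0, "MM*")
  expect_error(six_frame_translate(""), "non-empty")
  # codons containing N translate to X
  expect_equal(six_frame_translate("ATGNATAAA")$F0, "MXK")
})

test_that("hit filtering removes spans under 300 nt, preserving order", {
  h <- data.frame(scaffold = "s", start = c(0L, 500L, 1200L),
                  end = c(299L, 800L, 1600L), strand = "+", frame = 0L,
                  query = "q", score = 1, bitscore = 1,
                  evalue = c(1e-9, 1e-8, 1e-7))
  kept <- filter_hits(h)
  expect_equal(kept$start, c(500L, 1200L))  # span 299 removed, 300 kept
  expect_equal(nrow(filter_hits(h[0, ])), 0L)
  expect_equal(kept$evalue, c(1e-8, 1e-7))
})

test_that("hit merging unions same-strand neighbours within 50 nt", {
  mk <- function(start, end, strand = "+", frame = 0L, ev = 1e-10)
    data.frame(scaffold = "s", start = start, end = end, strand = strand,
               frame = frame, query = "q", score = 1, bitscore = 1,
               evalue = ev)
  two <- rbind(mk(0, 400), mk(300, 700))
  m <- merge_hits(two)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(0L, 700L))
  opp <- rbind(mk(0, 400, "+"), mk(0, 400, "-"))
  expect_equal(nrow(merge_hits(opp)), 2L)
  chain <- rbind(mk(0, 400), mk(430, 800), mk(840, 1200))
  expect_equal(nrow(merge_hits(chain)), 1L)
  # brute-force interval-union oracle on random hit sets
  set.seed(11)
  for (rep in 1:20) {
    starts <- sort(sample(0:5000, 8))
    ends <- starts + sample(100:600, 8, TRUE)
    h <- do.call(rbind, lapply(1:8, function(i) mk(starts[i], ends[i])))
    got <- merge_hits(h)
    # oracle: greedy union of sorted intervals with 50 nt tolerance
    n_groups <- 1L
    cur_end <- ends[1]
    for (i in 2:8) {
      if (starts[i] > cur_end + 50L) n_groups <- n_groups + 1L
      cur_end <- max(cur_end, ends[i])
    }
    expect_equal(nrow(got), n_groups)
  }
  # best e-value retained
  uneven <- rbind(mk(0, 400, ev = 1e-6), mk(300, 700, ev = 1e-20))
  expect_equal(merge_hits(uneven)$evalue, 1e-20)
})

test_that("ORF extension finds start/stop, disruptions, truncations", {
  set.seed(21)
  core <- back_translate(paste(rep("T", 300), collapse = ""))
  # clean ORF flanked by stop codons so background cannot extend it
  g1 <- genome_assembly(c(sc = paste0(rand_dna(90), "TAG",
                                      "ATG", core, "TAA", rand_dna(90))))
  cand <- extend_to_orf(g1, list(scaffold = "sc", start = 96L, end = 840L,
                                 strand = "+", frame = 96L %% 3L))
  expect_true(cand$has_start && cand$has_stop)
  expect_equal(nrow(cand$disruptions), 0L)
  expect_equal(nchar(cand$cds), 906L)  # ATG + 300 codons + stop

  # internal TGA at codon 100 (1-based) -> nonsense at offset 297
  cds <- paste0("ATG", core, "TAA")
  substr(cds, 298L, 300L) <- "TGA"
  g2 <- genome_assembly(c(sc = paste0(rand_dna(90), "TAG", cds, rand_dna(90))))
  cand2 <- extend_to_orf(g2, list(scaffold = "sc", start = 93L, end = 996L,
                                  strand = "+", frame = 0L))
  expect_equal(cand2$disruptions$type, "nonsense")
  expect_equal(cand2$disruptions$offset, 297L)

  # 20-N assembly gap upstream of a start-less ORF
  tail_orf <- paste0(back_translate(paste(rep("S", 150), collapse = "")), "TAA")
  g3 <- genome_assembly(c(sc = paste0(rand_dna(60), strrep("N", 20),
                                      tail_orf, rand_dna(60))))
  cand3 <- extend_to_orf(g3, list(scaffold = "sc", start = 80L, end = 530L,
                                  strand = "+", frame = 80L %% 3L))
  expect_false(cand3$has_start)
  expect_equal(cand3$truncation_cause, "assembly_gap")
  expect_true(cand3$has_stop)
  expect_error(extend_to_orf(g1, list(scaffold = "sc", start = 10L,
                                      end = 99999L, strand = "+", frame = 0L)),
               "bounds")
})

test_that("hydropathy TM prediction counts helices", {
  chg <- function(n) paste(rep("R", n), collapse = "")
  one <- paste0(chg(45), strrep("I", 25), chg(45))
  r1 <- predict_tm_helices(one)
  expect_equal(r1$count, 1L)
  expect_true(r1$spans$start[1] >= 40 && r1$spans$end[1] <= 75)
  expect_true(all(r1$spans$end - r1$spans$start + 1 >= 19) &&
                all(r1$spans$end - r1$spans$start + 1 <= 25))
  seven <- paste0(strrep("I", 25),
                  paste(rep(paste0(strrep("E", 15), strrep("I", 25)), 6),
                        collapse = ""))
  expect_equal(predict_tm_helices(seven)$count, 7L)
  expect_equal(predict_tm_helices(strrep("S", 150))$count, 0L)
  expect_error(predict_tm_helices(strrep("I", 50)), "too short")
  # bundled panel proteins are genuine 7-TM constructs
  counts <- vapply(synthetic_v1r_panel()$proteins,
                   function(p) predict_tm_helices(p)$count, integer(1))
  expect_true(all(counts == 7L))
})

test_that("classification implements the category rules", {
  mk <- function(cds_codons, has_start, has_stop, disr = 0L,
                 cause = "none", tm = 7L) {
    d <- if (disr > 0L) data.frame(type = rep("nonsense", disr),
                                   offset = seq_len(disr) * 3L)
         else data.frame(type = character(0), offset = integer(0))
    v1rpipe:::new_gene_candidate(
      scaffold = "s", start = 0L, end = cds_codons * 3L, strand = "+",
      cds = strrep("ACT", cds_codons), protein = strrep("T", cds_codons),
      has_start = has_start, has_stop = has_stop, disruptions = d,
      truncation_cause = cause, tm_count = tm, query = "q", evalue = 1e-10)
  }
  expect_equal(classify_candidate(mk(301, TRUE, TRUE))$category, "intact")
  # 269 coding codons (270 with stop) is below the floor
  expect_equal(classify_candidate(mk(270, TRUE, TRUE))$category,
               "short_complete")
  expect_equal(classify_candidate(mk(271, TRUE, TRUE))$category, "intact")
  expect_equal(classify_candidate(mk(301, TRUE, TRUE, tm = 6L))$category,
               "short_complete")
  # 150-codon open fragment at a scaffold edge, start only, 451 nt
  p <- mk(151, TRUE, FALSE, cause = "scaffold_edge")
  p$cds <- substr(strrep("ACT", 151), 1, 451)
  expect_equal(classify_candidate(p)$category, "partial")
  expect_equal(classify_candidate(mk(104, TRUE, TRUE, disr = 1L))$category,
               "pseudogene")
  # disrupted but too short -> dropped
  expect_equal(classify_candidate(mk(100, TRUE, TRUE, disr = 1L))$category,
               "dropped")
  # complete but no truncation cause and only one end -> not partial
  expect_equal(classify_candidate(mk(150, TRUE, FALSE))$category, "dropped")
})

test_that("identity confirmation picks the best labelled reference", {
  panel <- synthetic_v1r_panel()
  decoys <- synthetic_decoy_panel()
  refs <- query_panel(c(panel$proteins, decoys$proteins))
  mk <- function(prot) v1rpipe:::new_gene_candidate(
    scaffold = "s", start = 0L, end = 3L * nchar(prot), strand = "+",
    cds = "", protein = prot, has_start = TRUE, has_stop = TRUE,
    disruptions = data.frame(type = character(0), offset = integer(0)),
    truncation_cause = "none", tm_count = 7L, query = "q", evalue = 0)
  v1r_cand <- mk(panel$proteins[[1]])
  expect_true(as.logical(confirm_identity(v1r_cand, refs)))
  expect_equal(attr(confirm_identity(v1r_cand, refs), "best"), "V1R-syn1")
  decoy_cand <- mk(decoys$proteins[[2]])
  expect_false(as.logical(confirm_identity(decoy_cand, refs)))
  set.seed(3)
  junk <- mk(paste(sample(c("A", "G", "P", "S", "T"), 120, TRUE),
                   collapse = ""))
  expect_false(as.logical(confirm_identity(junk, refs)))
})

test_that("repertoire summary computes counts, means and medians", {
  per <- list(sp1 = rep("intact", 22), sp2 = rep("intact", 22),
              sp3 = rep("intact", 22), sp4 = rep("intact", 24),
              sp5 = rep("intact", 40))
  s <- summarize_repertoire(per)
  row <- s$stats[s$stats$category == "intact", ]
  expect_equal(row$mean, 26)
  expect_equal(row$median, 22)
  s2 <- summarize_repertoire(list(sp = c(rep("intact", 5), rep("partial", 2))))
  expect_equal(s2$per_species$functional, 7L)
  expect_equal(s2$per_species$intact + s2$per_species$partial,
               s2$per_species$functional)
  s3 <- summarize_repertoire(list(sp = character(0)))
  expect_true(all(s3$per_species[, -1] == 0))
  # even-length median rule: mean of the two central values
  s4 <- summarize_repertoire(list(a = rep("intact", 1), b = rep("intact", 2),
                                  c = rep("intact", 4), d = rep("intact", 9)))
  expect_equal(s4$stats$median[s4$stats$category == "intact"], 3)
})

test_that("built-in search matches the brute-force SW oracle and is quiet
           on random sequence", {
  set.seed(31)
  q <- query_panel(c(q1 = paste(sample(rownames(v1rpipe:::blosum62())[1:20],
                                       40, TRUE), collapse = "")))
  # genome embedding the back-translated query: self-match recovered
  emb <- paste0(rand_dna(150), back_translate(q$proteins[[1]]), rand_dna(150))
  g <- genome_assembly(c(sc = emb))
  hits <- translated_search(g, q, evalue_cutoff = 1e-3)
  expect_true(nrow(hits) >= 1L)
  top <- hits[which.min(hits$evalue), ]
  expect_true(top$start <= 150 && top$end >= 150 + 120)
  # engine score equals the independent SW oracle on each frame
  frames <- six_frame_translate(emb)
  best_oracle <- max(vapply(frames, function(fr)
    sw_oracle(q$proteins[[1]], fr), numeric(1)))
  expect_equal(top$score, best_oracle)
  # random 10 kb genome vs one query: nothing at 1e-5
  set.seed(32)
  g10 <- genome_assembly(c(r = rand_dna(10000)))
  expect_equal(nrow(translated_search(g10, q, 1e-5)), 0L)
  expect_error(translated_search(g10, query_panel(character(0))), "non-empty")
})

test_that("external tabular hits reproduce built-in candidates", {
  sim <- simulate_genome(seed = 9, n_intact = 1, n_partial = 1, n_pseudo = 1,
                         n_short = 0, n_decoys = 0, scaffold_len = 30000)
  panel <- synthetic_v1r_panel()
  cfg <- test_config()
  hits <- translated_search(sim$genome, panel, cfg$evalue_cutoff)
  # write the 12-column tabular equivalent and re-import
  tab <- data.frame(
    qseqid = hits$query, sseqid = hits$scaffold, pident = 100,
    length = (hits$end - hits$start) %/% 3L, mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = (hits$end - hits$start) %/% 3L,
    sstart = ifelse(hits$strand == "+", hits$start + 1L, hits$end),
    send = ifelse(hits$strand == "+", hits$end, hits$start + 1L),
    evalue = hits$evalue, bitscore = hits$bitscore)
  tf <- tempfile(fileext = ".tsv")
  write.table(tab, tf, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  imported <- read_blast_tab(tf, sim$genome)
  expect_equal(imported[c("scaffold", "start", "end", "strand", "frame")],
               hits[c("scaffold", "start", "end", "strand", "frame")],
               ignore_attr = TRUE)
  res_builtin <- suppressMessages(run_mining(cfg, sim$genome, panel))
  res_imported <- suppressMessages(run_mining(cfg, sim$genome, panel,
                                              hits = imported))
  expect_equal(res_imported$table[c("scaffold", "start", "end", "strand",
                                    "category")],
               res_builtin$table[c("scaffold", "start", "end", "strand",
                                   "category")])
})

test_that("strand symmetry: revcomp genome yields the same repertoire", {
  sim <- simulate_genome(seed = 5, n_intact = 1, n_partial = 0, n_pseudo = 1,
                         n_short = 0, n_decoys = 0, scaffold_len = 25000)
  panel <- synthetic_v1r_panel()
  cfg <- test_config()
  fwd <- suppressMessages(run_mining(cfg, sim$genome, panel))
  rc <- genome_assembly(vapply(sim$genome$seqs, dna_revcomp, character(1)))
  rev <- suppressMessages(run_mining(cfg, rc, panel))
  key <- function(res) sort(paste(res$table$category,
                                  vapply(res$candidates, `[[`, "",
                                         "cds")))
  expect_equal(key(rev), key(fwd))
})
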