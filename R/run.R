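# Top-level commands tying the stages into the three analyses, with
# stage logging and TSV/GFF3/FASTA outputs.

log_msg <- function(lines, msg) {
  message(msg)
  c(lines, msg)
}

#' Run the mining pipeline
#'
#' Search, filter, merge, extend, classify, confirm and name candidates;
#' optionally write GFF3 + CDS/protein FASTA + summary TSV + config +
#' stage log into `out_dir`. Given the same config, genome and queries
#' the outputs are byte-identical across runs.
#'
#' @param config [default_config()]
#' @param genome [genome_assembly()]
#' @param queries [query_panel()] of search queries
#' @param reference_set labelled [query_panel()] for identity
#'   confirmation (targets matching `target_pattern` plus decoys);
#'   defaults to `queries` plus the bundled synthetic decoys
#' @param out_dir output directory (created), or `NULL` for no files
#' @param species species label used in the summary
#' @param target_pattern regex marking target (V1R) reference names
#' @param hits optional precomputed hit table (e.g. from
#'   [read_blast_tab()]); skips the built-in search
#' @return list: `candidates` (confirmed, classified, named),
#'   `rejected` (failed identity confirmation), `table`, `summary`,
#'   `log`
#' @export
run_mining <- function(config, genome, queries,
                       reference_set = NULL, out_dir = NULL,
                       species = "species", target_pattern = "^V1R",
                       hits = NULL) {
  lg <- character(0)
  if (is.null(reference_set))
    reference_set <- query_panel(c(queries$proteins,
                                   synthetic_decoy_panel()$proteins))
  if (is.null(hits)) {
    hits <- translated_search(genome, queries, config$evalue_cutoff)
    lg <- log_msg(lg, sprintf("search: %d hits at e <= %g", nrow(hits),
                              config$evalue_cutoff))
  } else {
    hits <- hits[hits$evalue <= config$evalue_cutoff, , drop = FALSE]
    lg <- log_msg(lg, sprintf("imported hits: %d at e <= %g", nrow(hits),
                              config$evalue_cutoff))
  }
  kept <- filter_hits(hits, config$min_hit_nt)
  lg <- log_msg(lg, sprintf("length filter (>= %d nt): %d -> %d hits",
                            config$min_hit_nt, nrow(hits), nrow(kept)))
  loci <- merge_hits(kept, config$merge_nt)
  lg <- log_msg(lg, sprintf("merge (within %d nt): %d loci", config$merge_nt,
                            nrow(loci)))
  loci <- resolve_antisense_overlaps(loci)
  lg <- log_msg(lg, sprintf("antisense overlap resolution: %d loci",
                            nrow(loci)))
  cands <- list()
  rejected <- list()
  for (i in seq_len(nrow(loci))) {
    cand <- extend_to_orf(genome, loci[i, ], config$window_nt,
                          config$gap_min_n)
    cand <- classify_candidate(cand)
    if (cand$category == "dropped") next
    ok <- confirm_identity(cand, reference_set, target_pattern)
    cand$best_ref <- attr(ok, "best")
    if (ok) cands[[length(cands) + 1L]] <- cand
    else rejected[[length(rejected) + 1L]] <- cand
  }
  lg <- log_msg(lg, sprintf("classified: %d confirmed, %d rejected as non-target",
                            length(cands), length(rejected)))
  cands <- assign_names(cands)
  tab <- candidates_table(cands)
  summ <- summarize_repertoire(setNames(list(cands), species))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_gff3(cands, file.path(out_dir, "candidates.gff3"))
    if (length(cands)) {
      write_fasta(setNames(lapply(cands, `[[`, "cds"), tab$name),
                  file.path(out_dir, "candidates_cds.fasta"), "dna")
      prots <- vapply(cands, function(x) sub("\\*$", "", x$protein),
                      character(1))
      keep <- nzchar(prots) & !grepl("\\*", prots)
      if (any(keep))
        write_fasta(setNames(as.list(prots[keep]), tab$name[keep]),
                    file.path(out_dir, "candidates_protein.fasta"), "aa")
    }
    utils::write.table(summ$per_species,
                       file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_config(config, file.path(out_dir, "config.yaml"))
    writeLines(lg, file.path(out_dir, "mining.log"))
  }
  list(candidates = cands, rejected = rejected, table = tab,
       summary = summ, log = lg)
}

#' Write candidates as GFF3
#'
#' Coordinates are 1-based inclusive; attributes carry the category,
#' disruption evidence and TM count.
#'
#' @param cands list of classified `gene_candidate`s
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gff3 <- function(cands, path) {
  lines <- "##gff-version 3"
  for (x in cands) {
    disr <- if (nrow(x$disruptions)) paste(
      sprintf("%s@%d", x$disruptions$type, x$disruptions$offset),
      collapse = ",") else "none"
    attrs <- sprintf("ID=%s;category=%s;disruptions=%s;tm_count=%s;truncation=%s",
                     x$name %||% "candidate", x$category, disr,
                     ifelse(is.na(x$tm_count), "NA", x$tm_count),
                     x$truncation_cause)
    lines <- c(lines, paste(x$scaffold, "v1rpipe", "gene",
                            x$start + 1L, x$end, ".", x$strand, ".",
                            attrs, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Run the contrast analysis
#'
#' Contrasts of intact and of intact+partial (functional) counts against
#' lifestyle-code contrasts, each with Spearman's rho and two-tailed p,
#' plus the contrast scatter tables.
#'
#' @param config [default_config()]
#' @param tree dated `phylo`
#' @param traits data.frame: `species, lifestyle, intact, functional`
#' @param out_dir optional output directory
#' @return list with elements `intact` and `functional` (each a
#'   [lifestyle_correlation()] result)
#' @export
run_pic <- function(config, tree, traits, out_dir = NULL) {
  res <- list(intact = lifestyle_correlation(tree, traits, "intact"),
              functional = lifestyle_correlation(tree, traits, "functional"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    rep <- data.frame(
      which = c("intact", "functional"),
      rho = c(res$intact$rho, res$functional$rho),
      p_two_tailed = c(res$intact$p, res$functional$p),
      n_contrasts = c(res$intact$n, res$functional$n),
      slope_through_origin = c(res$intact$slope_through_origin,
                               res$functional$slope_through_origin))
    utils::write.table(rep, file.path(out_dir, "pic_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (w in c("intact", "functional"))
      utils::write.table(res[[w]]$contrasts,
                         file.path(out_dir, paste0("contrasts_", w, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    write_config(config, file.path(out_dir, "config.yaml"))
  }
  res
}

#' Mann-Whitney U test (two-tailed)
#'
#' Normal approximation with tie correction; exact (via the null U
#' distribution) when the combined sample size is at most 20 and there
#' are no ties.
#'
#' @param x,y numeric samples
#' @return list: `U`, `p`, `method`
#' @export
mann_whitney_u <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (n1 + n2 <= 20 && !ties) {
    p <- min(1, 2 * min(stats::pwilcox(U, n1, n2),
                        1 - stats::pwilcox(U - 1, n1, n2)))
    return(list(U = U, p = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  tie_tab <- table(r)
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  z <- (U - mu) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal approximation with tie correction")
}

#' Run the population-genetic analysis
#'
#' For each locus: per-population diversity (n, S, pi, theta) and
#' neutrality tests (D, D* with coalescent p), and between-population
#' differentiation (Hudson's FST, Snn with permutation p, FDR-adjusted
#' across loci). Cross-locus summaries: paired t-test of per-locus pi
#' between the populations, Mann-Whitney U of pi between receptor and
#' noncoding loci, and Fisher comparison of the fractions of
#' significantly differentiated loci.
#'
#' @param config [default_config()] (uses `coalescent_reps`,
#'   `permutation_reps`, `fdr_alpha`, `seed`)
#' @param v1r_loci named list of coding [pop_alignment()]s
#' @param noncoding_loci optional named list of noncoding
#'   [pop_alignment()]s
#' @param out_dir optional output directory
#' @return list: `diversity` (per locus x population), `differentiation`
#'   (per locus), `cross` (cross-locus tests)
#' @export
run_popgen <- function(config, v1r_loci, noncoding_loci = NULL,
                       out_dir = NULL) {
  analyse_group <- function(loci, group) {
    div <- list()
    diff <- list()
    for (nm in names(loci)) {
      aln <- loci[[nm]]
      pops <- unique(aln$pop)
      for (pp in pops) {
        sub <- subset_population(aln, pp)
        nt <- neutrality_test(sub, config$coalescent_reps,
                              seed = config$seed + length(div))
        div[[length(div) + 1L]] <- data.frame(
          group = group, locus = nm, population = pp, n = nrow(sub$mat),
          S = nt$S, pi = nucleotide_diversity(sub),
          theta_w = watterson_theta(sub), tajima_d = nt$tajima_d,
          p_tajima = nt$p_tajima, fu_li_dstar = nt$fu_li_dstar,
          p_fuli = nt$p_fuli, stringsAsFactors = FALSE)
      }
      fst <- hudson_fst(aln)
      snn <- snn_test(aln, config$permutation_reps,
                      seed = config$seed + 7919L + length(diff))
      diff[[length(diff) + 1L]] <- data.frame(
        group = group, locus = nm,
        fst = ifelse(fst$fst_defined, fst$fst, NA_real_),
        fst_defined = fst$fst_defined, snn = snn$snn, p_snn = snn$p,
        stringsAsFactors = FALSE)
    }
    list(div = do.call(rbind, div), diff = do.call(rbind, diff))
  }
  v1r <- analyse_group(v1r_loci, "V1R")
  nc <- if (!is.null(noncoding_loci))
    analyse_group(noncoding_loci, "noncoding") else NULL
  diversity <- rbind(v1r$div, if (!is.null(nc)) nc$div)
  differentiation <- rbind(v1r$diff, if (!is.null(nc)) nc$diff)
  # FDR across loci, separately per group (receptor vs noncoding family)
  differentiation$p_fdr <- NA_real_
  for (g in unique(differentiation$group)) {
    ii <- differentiation$group == g
    differentiation$p_fdr[ii] <- fdr_adjust(differentiation$p_snn[ii])
  }
  differentiation$significant <- differentiation$p_fdr < config$fdr_alpha

  cross <- list()
  pops <- unique(diversity$population)
  if (length(pops) == 2L) {
    v <- diversity[diversity$group == "V1R", ]
    pi1 <- v$pi[v$population == pops[1]]
    pi2 <- v$pi[v$population == pops[2]]
    if (length(pi1) == length(pi2) && length(pi1) > 1L)
      cross$paired_t_pi <- stats::t.test(pi1, pi2, paired = TRUE)$p.value
  }
  if (!is.null(nc)) {
    for (pp in pops) {
      v <- diversity$pi[diversity$group == "V1R" &
                          diversity$population == pp]
      w <- diversity$pi[diversity$group == "noncoding" &
                          diversity$population == pp]
      cross[[paste0("mwu_pi_", pp)]] <- mann_whitney_u(v, w)$p
    }
    a <- sum(differentiation$significant[differentiation$group == "V1R"],
             na.rm = TRUE)
    b <- sum(differentiation$group == "V1R")
    cc <- sum(differentiation$significant[differentiation$group == "noncoding"],
              na.rm = TRUE)
    d <- sum(differentiation$group == "noncoding")
    cross$fisher_significant_fraction <-
      fisher_exact_2x2(a, b - a, cc, d - cc)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(diversity, file.path(out_dir, "diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(differentiation,
                       file.path(out_dir, "differentiation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(yaml::as.yaml(cross), file.path(out_dir, "cross_locus.yaml"))
    write_config(config, file.path(out_dir, "config.yaml"))
  }
  list(diversity = diversity, differentiation = differentiation,
       cross = cross)
}
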