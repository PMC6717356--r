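# ORF extension and candidate classification. Loci found by homology are
# extended in-frame in both directions to the putative start and stop
# codons, recording nonsense/frameshift evidence and the cause of any
# truncation (scaffold edge or assembly gap); candidates are then
# classified intact / partial / pseudogene / short_complete.

#' @keywords internal
new_gene_candidate <- function(scaffold, start, end, strand, cds, protein,
                               has_start, has_stop, disruptions,
                               truncation_cause, tm_count, query, evalue,
                               name = NA_character_) {
  structure(list(
    scaffold = scaffold, start = start, end = end, strand = strand,
    category = NA_character_, cds = cds, protein = protein,
    has_start = has_start, has_stop = has_stop, disruptions = disruptions,
    truncation_cause = truncation_cause, tm_count = tm_count,
    query = query, evalue = evalue, name = name), class = "gene_candidate")
}

#' @export
print.gene_candidate <- function(x, ...) {
  cat(sprintf("<gene_candidate> %s:%d-%d(%s) %s cds=%dnt start=%s stop=%s disruptions=%d cause=%s tm=%s\n",
              x$scaffold, x$start, x$end, x$strand,
              ifelse(is.na(x$category), "(unclassified)", x$category),
              nchar(x$cds), x$has_start, x$has_stop,
              nrow(x$disruptions), x$truncation_cause,
              ifelse(is.na(x$tm_count), "NA", x$tm_count)))
  invisible(x)
}

no_disruptions <- function()
  data.frame(type = character(0), offset = integer(0), stringsAsFactors = FALSE)

# codon (3 nt) at 0-based oriented position p, or NA if out of bounds
codon_at <- function(seq, p) {
  if (p < 0L || p + 3L > nchar(seq)) return(NA_character_)
  substr(seq, p + 1L, p + 3L)
}

# does the codon at 0-based p overlap a run of >= min_run N's?
in_gap <- function(gaps, p) {
  if (nrow(gaps) == 0L) return(FALSE)
  any(gaps[, "start"] <= p + 3L & gaps[, "end"] >= p + 1L)
}

#' Extend a locus in-frame to a putative start and stop codon
#'
#' Walks in-frame from the homology locus: upstream to the nearest
#' in-frame `ATG` (stopping at any in-frame stop codon first), downstream
#' from the locus end to the nearest in-frame stop codon, each within
#' `window_nt`. Extension that runs off the scaffold or into an assembly
#' gap (a run of at least `gap_min_n` `N`s) before finding the codon sets
#' `truncation_cause` to `"scaffold_edge"` or `"assembly_gap"`. In-frame
#' stop codons internal to the resulting span are recorded as `nonsense`
#' disruptions; inconsistent reading frames among the locus' merged hits
#' are recorded as a `frameshift` disruption.
#'
#' @param genome a [genome_assembly()]
#' @param locus one-row data.frame from [merge_hits()] (or a list with the
#'   same fields `scaffold, start, end, strand, frame`, optionally
#'   `frames`, `query`, `evalue`)
#' @param window_nt maximum extension in each direction (default 3000)
#' @param gap_min_n minimum N-run length treated as an assembly gap
#' @return an (unclassified) `gene_candidate`
#' @export
extend_to_orf <- function(genome, locus, window_nt = 3000L, gap_min_n = 10L) {
  locus <- as.list(locus)
  sc <- locus$scaffold
  if (!sc %in% names(genome$seqs)) stop("unknown scaffold: ", sc)
  L <- nchar(genome$seqs[[sc]])
  if (locus$start < 0L || locus$end > L || locus$start >= locus$end)
    stop("locus outside scaffold bounds")
  strand <- locus$strand
  seq <- if (strand == "+") genome$seqs[[sc]] else dna_revcomp(genome$seqs[[sc]])
  # anchor the extension on the best-evidence hit span when available:
  # weaker overlapping hits from other family members can overshoot the
  # true gene ends
  a_start <- locus$best_start %||% locus$start
  a_end <- locus$best_end %||% locus$end
  if (is.na(a_start) || is.na(a_end)) { a_start <- locus$start; a_end <- locus$end }
  # oriented 0-based half-open locus coordinates
  o_start <- if (strand == "+") a_start else L - a_end
  o_end <- if (strand == "+") a_end else L - a_start
  frame <- locus$frame
  gaps <- n_runs(seq, gap_min_n)

  # homology alignments are not trusted across assembly gaps: if the
  # locus span contains a gap, keep its largest gap-free segment
  ov <- gaps[gaps[, "start"] <= o_end & gaps[, "end"] > o_start, ,
             drop = FALSE]
  if (nrow(ov)) {
    bounds <- c(o_start, as.vector(t(cbind(ov[, "start"] - 1L, ov[, "end"]))),
                o_end)
    seg_start <- bounds[seq(1, length(bounds), by = 2)]
    seg_end <- bounds[seq(2, length(bounds), by = 2)]
    keep <- which.max(pmax(0L, seg_end - seg_start))
    o_start <- max(o_start, seg_start[keep])
    o_end <- min(o_end, seg_end[keep])
  }

  # first in-frame codon position at or before the locus start
  a0 <- o_start - ((o_start - frame) %% 3L)
  if (a0 < 0L) a0 <- a0 + 3L

  # upstream: locate the nearest in-frame stop (or scaffold edge /
  # assembly gap) above the locus start, then take the first ATG after
  # it; the true start codon may lie just inside the aligned span when
  # the alignment overshoots it
  has_start <- FALSE
  cause <- "none"
  cds_start <- max(a0, 0L)
  stop_bound <- max(a0 - window_nt, frame %% 3L)
  p <- a0 - 3L
  while (p >= a0 - window_nt) {
    if (p < 0L) { cause <- "scaffold_edge"; break }
    cod <- codon_at(seq, p)
    if (grepl("N", cod)) {
      if (in_gap(gaps, p)) { cause <- "assembly_gap"; break }
    } else if (cod %in% STOP_CODONS) { stop_bound <- p + 3L; break }
    p <- p - 3L
  }
  if (cause == "none") {
    p <- stop_bound
    while (p <= o_end - 3L) {
      cod <- codon_at(seq, p)
      if (!is.na(cod) && !grepl("N", cod) && cod == "ATG") {
        has_start <- TRUE
        cds_start <- p
        break
      }
      p <- p + 3L
    }
  }

  # downstream from the locus end: nearest in-frame stop codon
  e0 <- a0 + 3L * ceiling((o_end - a0) / 3)
  has_stop <- FALSE
  cds_end <- e0
  p <- e0
  while (p <= e0 + window_nt) {
    cod <- codon_at(seq, p)
    if (is.na(cod)) {
      if (cause == "none") cause <- "scaffold_edge"
      cds_end <- p
      break
    }
    if (grepl("N", cod) && in_gap(gaps, p)) {
      if (cause == "none") cause <- "assembly_gap"
      cds_end <- p
      break
    }
    if (!grepl("N", cod) && cod %in% STOP_CODONS) {
      has_stop <- TRUE
      cds_end <- p + 3L
      break
    }
    p <- p + 3L
  }
  if (!has_stop && p > e0 + window_nt) cds_end <- p

  disr <- no_disruptions()
  # internal in-frame stops (between start and the final stop codon)
  last_internal <- cds_end - (if (has_stop) 6L else 3L)
  if (last_internal >= cds_start) {
    for (q in seq(cds_start, last_internal, by = 3L)) {
      cod <- codon_at(seq, q)
      if (!is.na(cod) && !grepl("N", cod) && cod %in% STOP_CODONS)
        disr <- rbind(disr, data.frame(type = "nonsense",
                                       offset = q - cds_start,
                                       stringsAsFactors = FALSE))
    }
  }
  # frame inconsistency among merged hit fragments
  fr <- locus$frames
  if (is.list(fr)) fr <- fr[[1]]
  if (!is.null(fr) && length(unique(fr)) > 1L)
    disr <- rbind(disr, data.frame(type = "frameshift",
                                   offset = o_start - cds_start,
                                   stringsAsFactors = FALSE))

  cds <- substr(seq, cds_start + 1L, cds_end)
  protein <- if (nchar(cds) >= 3L) translate_dna(cds) else ""
  prot_clean <- sub("\\*$", "", protein)
  tm <- if (nchar(gsub("[X*]", "", prot_clean)) >= 100L &&
            !grepl("\\*", prot_clean))
    predict_tm_helices(prot_clean)$count else NA_integer_

  g_start <- if (strand == "+") cds_start else L - cds_end
  g_end <- if (strand == "+") cds_end else L - cds_start
  new_gene_candidate(
    scaffold = sc, start = g_start, end = g_end, strand = strand,
    cds = cds, protein = protein, has_start = has_start,
    has_stop = has_stop, disruptions = disr, truncation_cause = cause,
    tm_count = tm, query = locus$query %||% NA_character_,
    evalue = locus$evalue %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify a candidate gene
#'
#' Rules: *intact* = at least 270 coding codons (the stop codon does not
#' count), a start and a stop codon, no nonsense/frameshift disruption,
#' and seven predicted transmembrane helices; *partial* = undisrupted ORF
#' longer than 300 nt with exactly one of start/stop, truncated by a
#' scaffold edge or assembly gap; *pseudogene* = more than 300 nt with at
#' least one disruption; complete undisrupted ORFs shorter than 270
#' codons (or lacking seven TM helices) fall into *short_complete*;
#' anything else is *dropped*.
#'
#' @param cand a `gene_candidate` from [extend_to_orf()]
#' @return the candidate with `category` set
#' @export
classify_candidate <- function(cand) {
  stopifnot(inherits(cand, "gene_candidate"))
  n_cds <- nchar(cand$cds)
  n_codons <- n_cds %/% 3L - (if (cand$has_stop) 1L else 0L)
  disrupted <- nrow(cand$disruptions) > 0L
  complete <- cand$has_start && cand$has_stop
  cand$category <-
    if (disrupted && n_cds > 300L) "pseudogene"
    else if (!disrupted && complete && n_codons >= 270L &&
             !is.na(cand$tm_count) && cand$tm_count == 7L) "intact"
    else if (!disrupted && xor(cand$has_start, cand$has_stop) &&
             n_cds > 300L && cand$truncation_cause != "none") "partial"
    else if (!disrupted && complete && n_cds > 300L) "short_complete"
    else "dropped"
  cand
}

#' Confirm candidate identity against a labelled reference set
#'
#' The candidate's translation is aligned locally (BLOSUM62, 11/1)
#' against every reference protein; the candidate is confirmed iff its
#' best-scoring reference matches `target_pattern` and the raw score is
#' at least `score_floor`.
#'
#' @param cand `gene_candidate`
#' @param reference_set [query_panel()] bundling target (V1R) and decoy
#'   (non-V1R GPCR) proteins
#' @param target_pattern regex identifying target reference names
#' @param score_floor minimum raw alignment score
#' @return logical, with attribute `best` = best reference name
#' @export
confirm_identity <- function(cand, reference_set, target_pattern = "^V1R",
                             score_floor = 60) {
  stopifnot(inherits(reference_set, "query_panel"))
  prot <- sub("\\*$", "", cand$protein)
  if (!nzchar(prot)) return(structure(FALSE, best = NA_character_))
  prot <- gsub("\\*", "X", prot)  # internal stops align as unknowns
  scores <- vapply(reference_set$proteins, function(ref)
    align_one(prot, ref)$score, numeric(1))
  best <- names(which.max(scores))
  ok <- max(scores) >= score_floor && grepl(target_pattern, best)
  structure(ok, best = best)
}

#' Assign repertoire names from best reference hits
#'
#' Each confirmed candidate is named after its best-matching reference
#' with an ordinal suffix in genomic order (`<ref>-1`, `<ref>-2`, ...).
#'
#' @param cands list of `gene_candidate`s with `best` attribute recorded
#'   in field `best_ref`
#' @return the list with `name` fields filled
#' @export
assign_names <- function(cands) {
  refs <- vapply(cands, function(x) x$best_ref %||% x$query, character(1))
  for (r in unique(refs)) {
    idx <- which(refs == r)
    for (k in seq_along(idx)) cands[[idx[k]]]$name <- sprintf("%s-%d", r, k)
  }
  cands
}

#' Tabulate candidates
#'
#' @param cands list of classified `gene_candidate`s
#' @return data.frame, one row per candidate
#' @export
candidates_table <- function(cands) {
  if (length(cands) == 0L)
    return(data.frame(name = character(0), scaffold = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), category = character(0),
                      cds_len = integer(0), n_disruptions = integer(0),
                      truncation_cause = character(0), tm_count = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(cands, function(x) data.frame(
    name = x$name %||% NA_character_, scaffold = x$scaffold, start = x$start,
    end = x$end, strand = x$strand, category = x$category,
    cds_len = nchar(x$cds), n_disruptions = nrow(x$disruptions),
    truncation_cause = x$truncation_cause,
    tm_count = ifelse(is.na(x$tm_count), NA_integer_, x$tm_count),
    stringsAsFactors = FALSE)))
}

#' Summarize repertoires across species
#'
#' Counts intact, partial, pseudogene, short-complete and functional
#' (= intact + partial) genes per species, with the mean and median of
#' each category across species. The median of an even-length count list
#' is the mean of the two central values.
#'
#' @param per_species named list: species -> classified candidate list,
#'   or species -> character vector of categories
#' @return list with `per_species` (data.frame of counts) and `stats`
#'   (data.frame of mean/median per category)
#' @export
summarize_repertoire <- function(per_species) {
  cats <- c("intact", "partial", "pseudogene", "short_complete")
  rows <- lapply(names(per_species), function(sp) {
    x <- per_species[[sp]]
    cat_vec <- if (is.character(x)) x
               else vapply(x, function(k) k$category, character(1))
    cnt <- vapply(cats, function(cc) sum(cat_vec == cc), integer(1))
    data.frame(species = sp, intact = cnt[1], partial = cnt[2],
               pseudogene = cnt[3], short_complete = cnt[4],
               functional = cnt[1] + cnt[2], stringsAsFactors = FALSE)
  })
  per <- if (length(rows)) do.call(rbind, rows)
         else data.frame(species = character(0), intact = integer(0),
                         partial = integer(0), pseudogene = integer(0),
                         short_complete = integer(0), functional = integer(0))
  stat_cols <- c(cats, "functional")
  stats <- data.frame(
    category = stat_cols,
    mean = vapply(stat_cols, function(cc)
      if (nrow(per)) mean(per[[cc]]) else 0, numeric(1)),
    median = vapply(stat_cols, function(cc)
      if (nrow(per)) stats::median(per[[cc]]) else 0, numeric(1)),
    stringsAsFactors = FALSE)
  list(per_species = per, stats = stats)
}
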