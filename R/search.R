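# Translated homology search: each protein query is aligned locally
# (Smith-Waterman, BLOSUM62, affine gaps 11/1) against all six translation
# frames of every scaffold; significance is Karlin-Altschul. This built-in
# engine keeps the pipeline free of external binaries; an importer for
# external translated-BLAST tabular output provides the production path.

# Karlin-Altschul parameters for gapped BLOSUM62 with gap open 11 /
# extend 1 (the BLAST defaults for this scoring system).
KA_LAMBDA <- 0.267
KA_K <- 0.041

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Karlin-Altschul e-value for a raw local alignment score
#'
#' @param score raw Smith-Waterman score (BLOSUM62, 11/1)
#' @param m query length (residues)
#' @param n_db effective database length in residues; for a genome search
#'   this is `total nt * 2 strands / 3`
#' @return expectation value
#' @export
karlin_altschul_evalue <- function(score, m, n_db) {
  KA_K * m * n_db * exp(-KA_LAMBDA * score)
}

#' @rdname karlin_altschul_evalue
#' @export
bit_score <- function(score) (KA_LAMBDA * score - log(KA_K)) / log(2)

empty_hits <- function() {
  data.frame(scaffold = character(0), start = integer(0), end = integer(0),
             strand = character(0), frame = integer(0), query = character(0),
             score = numeric(0), bitscore = numeric(0), evalue = numeric(0),
             stringsAsFactors = FALSE)
}

# One local alignment of query vs a frame translation; returns NULL or
# list(score, aa_start, aa_end).
align_one <- function(query_aa, subject_aa) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query_aa), Biostrings::AAString(subject_aa),
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1)
  list(score = Biostrings::score(al),
       aa_start = IRanges::start(Biostrings::subject(al)@range),
       aa_end = IRanges::end(Biostrings::subject(al)@range))
}

# Map a 1-based aa interval in frame `frame` of a scaffold of length L to
# 0-based half-open genomic coordinates.
frame_to_genomic <- function(aa_start, aa_end, frame, strand, L) {
  if (strand == "+") {
    c(start = frame + 3L * (aa_start - 1L), end = frame + 3L * aa_end)
  } else {
    c(start = L - (frame + 3L * aa_end), end = L - (frame + 3L * (aa_start - 1L)))
  }
}

#' Translated search of a genome assembly with a protein query panel
#'
#' Smith-Waterman local alignment of each query against all six frames of
#' each scaffold (BLOSUM62, gap open 11, extend 1), keeping every
#' non-overlapping alignment whose Karlin-Altschul e-value is at or below
#' `evalue_cutoff`. Multiple hits per frame are recovered by masking each
#' reported alignment and re-aligning.
#'
#' @param genome a [genome_assembly()]
#' @param panel a [query_panel()]
#' @param evalue_cutoff e-value threshold (default `1e-5`)
#' @param max_hits_per_frame safety cap on the masking iteration
#' @return data.frame of hits: `scaffold, start, end` (0-based half-open
#'   genomic), `strand`, `frame` (0-2 on its strand), `query`, `score`
#'   (raw), `bitscore`, `evalue`
#' @export
translated_search <- function(genome, panel, evalue_cutoff = 1e-5,
                              max_hits_per_frame = 20L) {
  stopifnot(inherits(genome, "genome_assembly"), inherits(panel, "query_panel"))
  n_db <- sum(nchar(genome$seqs)) * 2 / 3
  rows <- list()
  for (sc in names(genome$seqs)) {
    seq <- genome$seqs[[sc]]
    L <- nchar(seq)
    frames <- six_frame_translate(seq)
    for (fi in seq_along(frames)) {
      strand <- if (fi <= 3L) "+" else "-"
      frame <- (fi - 1L) %% 3L
      subj0 <- frames[[fi]]
      if (nchar(subj0) < 5L) next
      for (q in names(panel$proteins)) {
        qaa <- panel$proteins[[q]]
        subj <- subj0
        for (iter in seq_len(max_hits_per_frame)) {
          al <- align_one(qaa, subj)
          ev <- karlin_altschul_evalue(al$score, nchar(qaa), n_db)
          if (!is.finite(al$score) || ev > evalue_cutoff) break
          g <- frame_to_genomic(al$aa_start, al$aa_end, frame, strand, L)
          rows[[length(rows) + 1L]] <- data.frame(
            scaffold = sc, start = unname(g["start"]), end = unname(g["end"]),
            strand = strand, frame = frame, query = q,
            score = al$score, bitscore = bit_score(al$score), evalue = ev,
            stringsAsFactors = FALSE)
          # mask the reported span so further alignments cannot reuse it
          substr(subj, al$aa_start, al$aa_end) <-
            strrep("*", al$aa_end - al$aa_start + 1L)
        }
      }
    }
  }
  if (length(rows) == 0L) return(empty_hits())
  out <- do.call(rbind, rows)
  out[order(out$scaffold, out$strand, out$start), , drop = FALSE]
}

#' Discard short hits
#'
#' Hits whose genomic span is shorter than `min_nt` (default 300 bp) are
#' removed; order is preserved.
#'
#' @param hits hit data.frame from [translated_search()]
#' @param min_nt minimum span in nucleotides
#' @return filtered data.frame
#' @export
filter_hits <- function(hits, min_nt = 300L) {
  stopifnot(min_nt > 0)
  if (nrow(hits) == 0L) return(hits)
  hits[(hits$end - hits$start) >= min_nt, , drop = FALSE]
}

#' Merge hits into candidate loci
#'
#' Hits on the same scaffold and strand whose spans overlap or lie within
#' `merge_nt` of each other are merged into one locus spanning their
#' union. The lowest e-value (and its query and frame) is retained;
#' the set of member reading frames is kept for frameshift detection.
#'
#' @param hits hit data.frame
#' @param merge_nt maximum gap between mergeable hits (default 50)
#' @return data.frame of loci: `scaffold, start, end, strand, frame,
#'   query, evalue, n_hits` plus list-column `frames`
#' @export
merge_hits <- function(hits, merge_nt = 50L) {
  if (nrow(hits) == 0L)
    return(cbind(empty_hits()[c("scaffold", "start", "end", "strand",
                                "frame", "query", "evalue")],
                 data.frame(n_hits = integer(0))))
  hits <- hits[order(hits$scaffold, hits$strand, hits$start), , drop = FALSE]
  key <- paste(hits$scaffold, hits$strand)
  out <- list()
  for (k in unique(key)) {
    h <- hits[key == k, , drop = FALSE]
    grp <- integer(nrow(h))
    g <- 1L
    grp[1] <- g
    cur_end <- h$end[1]
    for (i in seq_len(nrow(h))[-1]) {
      if (h$start[i] <= cur_end + merge_nt) {
        grp[i] <- g
        cur_end <- max(cur_end, h$end[i])
      } else {
        g <- g + 1L
        grp[i] <- g
        cur_end <- h$end[i]
      }
    }
    for (g2 in unique(grp)) {
      hh <- h[grp == g2, , drop = FALSE]
      best <- which.min(hh$evalue)
      loc <- data.frame(
        scaffold = hh$scaffold[1], start = min(hh$start), end = max(hh$end),
        strand = hh$strand[1], frame = hh$frame[best], query = hh$query[best],
        evalue = hh$evalue[best], n_hits = nrow(hh),
        best_start = hh$start[best], best_end = hh$end[best],
        stringsAsFactors = FALSE)
      loc$frames <- list(sort(unique(hh$frame)))
      out[[length(out) + 1L]] <- loc
    }
  }
  res <- do.call(rbind, out)
  res[order(res$scaffold, res$strand, res$start), , drop = FALSE]
}

#' Resolve antisense overlaps among merged loci
#'
#' Reverse complements of receptor ORFs stay hydrophobic-rich and can
#' attract weak antisense hits over a real gene. Where loci on the same
#' scaffold overlap on opposite strands, only the locus with the best
#' (lowest) e-value is kept (one candidate per genomic locus); loci are
#' processed greedily in e-value order.
#'
#' @param loci data.frame from [merge_hits()]
#' @return filtered data.frame, original order preserved
#' @export
resolve_antisense_overlaps <- function(loci) {
  if (nrow(loci) <= 1L) return(loci)
  keep <- logical(nrow(loci))
  for (i in order(loci$evalue)) {
    j <- which(keep & loci$scaffold == loci$scaffold[i] &
                 loci$strand != loci$strand[i] &
                 loci$start < loci$end[i] & loci$end > loci$start[i])
    if (!length(j)) keep[i] <- TRUE
  }
  loci[keep, , drop = FALSE]
}

#' Import external translated-BLAST tabular output
#'
#' Reads the standard 12-column tabular format (`qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore`) as
#' produced by `tblastn -outfmt 6` and converts it to the hit table used
#' by the built-in engine. Subject coordinates are 1-based inclusive on
#' the plus strand with `sstart > send` indicating a minus-strand hit.
#'
#' @param path tabular file
#' @param genome the searched [genome_assembly()] (needed to recover the
#'   reading frame on the minus strand)
#' @return hit data.frame as from [translated_search()] (`score` is `NA`;
#'   filtering and merging only use coordinates and e-values)
#' @export
read_blast_tab <- function(path, genome) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tb <- utils::read.delim(path, header = FALSE, col.names = cols,
                          stringsAsFactors = FALSE)
  if (nrow(tb) == 0L) return(empty_hits())
  L <- setNames(nchar(genome$seqs), names(genome$seqs))
  strand <- ifelse(tb$sstart <= tb$send, "+", "-")
  start0 <- ifelse(strand == "+", tb$sstart - 1L, tb$send - 1L)
  end0 <- ifelse(strand == "+", tb$send, tb$sstart)
  Ls <- L[tb$sseqid]
  frame <- ifelse(strand == "+", start0 %% 3L, (Ls - end0) %% 3L)
  out <- data.frame(
    scaffold = tb$sseqid, start = as.integer(start0), end = as.integer(end0),
    strand = strand, frame = as.integer(frame), query = tb$qseqid,
    score = NA_real_, bitscore = tb$bitscore, evalue = tb$evalue,
    stringsAsFactors = FALSE)
  out[order(out$scaffold, out$strand, out$start), , drop = FALSE]
}
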