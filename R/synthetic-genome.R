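# Synthetic mining substrate: genomes with implanted V1R-like genes
# (intact, edge/gap-truncated partial, nonsense/frameshift pseudogene,
# short-complete) among decoy GPCR-like ORFs, plus the reference protein
# panels the genes derive from. Everything is a pure function of its
# seed; regenerated outputs are byte-identical.

HYDROPHOBIC_AA <- c("I", "L", "V", "F", "A", "M")
POLAR_AA <- c("S", "T", "N", "Q", "D", "E", "K", "R", "G", "H", "Y", "P")

# a 7-TM-like protein: M + polar N-term + 7 x (22 hydrophobic + 17 polar)
# + polar C-term; 318 aa, designed so the Kyte-Doolittle predictor finds
# exactly 7 helices
random_7tm_protein <- function() {
  parts <- c("M", sample(POLAR_AA, 24, replace = TRUE))
  for (k in 1:7) {
    parts <- c(parts, sample(HYDROPHOBIC_AA, 22, replace = TRUE),
               if (k < 7) sample(POLAR_AA, 17, replace = TRUE))
  }
  parts <- c(parts, sample(POLAR_AA, 20, replace = TRUE))
  paste(parts, collapse = "")
}

#' Synthetic V1R-like reference panel
#'
#' Deterministic panel of seven-transmembrane receptor-like proteins used
#' as search queries and identity references. These are synthetic
#' constructs, not database sequences.
#'
#' @param n panel size
#' @param seed generator seed (fixed default so the bundled panel is
#'   stable)
#' @return [query_panel()] with names `V1R-syn1..n`
#' @export
synthetic_v1r_panel <- function(n = 6L, seed = 20190830L) {
  with_seed(seed, {
    prot <- vapply(seq_len(n), function(i) random_7tm_protein(), character(1))
    names(prot) <- paste0("V1R-syn", seq_len(n))
    query_panel(prot)
  })
}

#' Synthetic decoy panel (non-V1R GPCR-like proteins)
#'
#' Same structural recipe as the V1R panel but an independent random
#' stream, standing in for unrelated seven-TM receptors (e.g. taste
#' receptors) used to test identity confirmation.
#'
#' @param n panel size
#' @param seed generator seed
#' @return [query_panel()] with names `T2R-syn1..n`
#' @export
synthetic_decoy_panel <- function(n = 4L, seed = 817L) {
  with_seed(seed, {
    prot <- vapply(seq_len(n), function(i) random_7tm_protein(), character(1))
    names(prot) <- paste0("T2R-syn", seq_len(n))
    query_panel(prot)
  })
}

# reverse genetic code: aa -> codons (stops excluded)
codon_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc <- Biostrings::GENETIC_CODE
      cache <<- split(names(gc), unname(gc))
    }
    cache
  }
})

#' Back-translate a protein with uniform synonymous codon choice
#' @param protein amino-acid string (no stops)
#' @return DNA string, `3 * nchar(protein)` nt
#' @export
back_translate <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  tab <- codon_table()
  paste(vapply(aa, function(a) {
    cods <- tab[[a]]
    if (is.null(cods)) stop("cannot back-translate residue ", a)
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# build one implant element; returns list(dna, truth fields)
build_element <- function(type, k, panel, decoys) {
  pick <- function(p) {
    i <- sample.int(length(p$proteins), 1L)
    list(name = names(p$proteins)[i], prot = p$proteins[[i]])
  }
  stopcod <- sample(STOP_CODONS, 1L)
  if (type == "decoy") {
    src <- pick(decoys)
    return(list(dna = paste0(back_translate(src$prot), stopcod),
                source = src$name, category = "decoy",
                disruption = "none", truncation = "none"))
  }
  src <- pick(panel)
  prot <- src$prot
  if (type == "intact") {
    list(dna = paste0(back_translate(prot), stopcod), source = src$name,
         category = "intact", disruption = "none", truncation = "none")
  } else if (type == "short_complete") {
    # complete ORF of ~200 codons: below the 270-codon intact floor
    list(dna = paste0(back_translate(substr(prot, 1, 200)), stopcod),
         source = src$name, category = "short_complete",
         disruption = "none", truncation = "none")
  } else if (type == "partial") {
    # 5'-truncated: drop the first 60 aa (start lost); stop retained
    list(dna = paste0(back_translate(substr(prot, 61, nchar(prot))), stopcod),
         source = src$name, category = "partial",
         disruption = "none",
         truncation = if (k %% 2L == 0L) "scaffold_edge" else "assembly_gap")
  } else if (type == "pseudogene") {
    dna <- paste0(back_translate(prot), stopcod)
    mid_codon <- nchar(prot) %/% 2L
    if (k %% 2L == 0L) {  # nonsense: premature stop mid-gene
      substr(dna, mid_codon * 3L + 1L, mid_codon * 3L + 3L) <- "TAA"
      disruption <- "nonsense"
    } else {              # frameshift: delete one nt mid-gene
      cut <- mid_codon * 3L
      dna <- paste0(substr(dna, 1, cut), substr(dna, cut + 2L, nchar(dna)))
      disruption <- "frameshift"
    }
    list(dna = dna, source = src$name, category = "pseudogene",
         disruption = disruption, truncation = "none")
  } else stop("unknown element type ", type)
}

#' Simulate a genome with implanted receptor genes
#'
#' Implants back-translated copies of the synthetic V1R panel into random
#' background sequence: `n_intact` complete ORFs, `n_partial` truncated
#' ORFs (alternating scaffold-edge and assembly-gap truncation, start
#' codon lost), `n_pseudo` disrupted ORFs (alternating premature-stop and
#' single-nucleotide-deletion frameshift), `n_short` complete-but-short
#' ORFs, and `n_decoys` decoy GPCR-like ORFs. Elements are placed on both
#' strands across several scaffolds, separated by at least 2 kb of
#' background.
#'
#' @param seed integer seed (the generator is a pure function of seed and
#'   parameters)
#' @param n_intact,n_partial,n_pseudo,n_short,n_decoys element counts
#' @param scaffold_len total genome length (nt), split across
#'   `max(2, ceiling(total elements / 3))` scaffolds
#' @param panel,decoys source panels (defaults: the bundled synthetic
#'   panels)
#' @return list: `genome` ([genome_assembly()]) and `truth` (data.frame:
#'   element, scaffold, start, end (0-based half-open, implanted region),
#'   strand, category, disruption, truncation, source)
#' @export
simulate_genome <- function(seed, n_intact = 3L, n_partial = 2L,
                            n_pseudo = 4L, n_short = 1L, n_decoys = 2L,
                            scaffold_len = 200000L,
                            panel = synthetic_v1r_panel(),
                            decoys = synthetic_decoy_panel()) {
  stopifnot(n_intact >= 0, n_partial >= 0, n_pseudo >= 0, n_short >= 0,
            n_decoys >= 0)
  with_seed(seed, {
    types <- c(rep("intact", n_intact), rep("partial", n_partial),
               rep("pseudogene", n_pseudo), rep("short_complete", n_short),
               rep("decoy", n_decoys))
    n_el <- length(types)
    n_sc <- max(2L, ceiling(n_el / 3))
    sc_len <- rep(scaffold_len %/% n_sc, n_sc)
    # elements, with per-type ordinals driving the alternation rules
    elements <- list()
    ord <- integer(0)
    for (ty in unique(types)) {
      idx <- which(types == ty)
      for (k in seq_along(idx))
        elements[[idx[k]]] <- build_element(ty, k, panel, decoys)
    }
    # spread elements over scaffolds; edge-truncated partials each claim
    # the left edge of their own scaffold
    edge_idx <- which(vapply(elements, function(e)
      e$truncation == "scaffold_edge", logical(1)))
    if (length(edge_idx) > n_sc)
      stop("more edge-truncated partials than scaffolds available")
    assign_sc <- integer(n_el)
    assign_sc[edge_idx] <- seq_along(edge_idx)
    rest <- setdiff(seq_len(n_el), edge_idx)
    if (length(rest))
      assign_sc[rest] <- sample(rep(seq_len(n_sc), length.out = length(rest)))
    gap_run <- strrep("N", 15L)
    scaffolds <- character(n_sc)
    truth <- list()
    for (s in seq_len(n_sc)) {
      idx <- which(assign_sc == s)
      # an edge-truncated partial, if present, goes first (position 0)
      ef <- intersect(idx, edge_idx)
      idx <- c(ef, setdiff(idx, ef))
      pieces <- character(0)
      pos <- 0L
      capacity <- sc_len[s]
      for (i in idx) {
        el <- elements[[i]]
        strand <- sample(c("+", "-"), 1L)
        at_edge <- el$truncation == "scaffold_edge" && pos == 0L
        lead <- if (at_edge) "" else {
          bg <- random_dna(2000L + sample.int(3000L, 1L))
          if (el$truncation == "assembly_gap") paste0(bg, gap_run) else bg
        }
        dna <- if (strand == "+") el$dna else dna_revcomp(el$dna)
        # gap-truncated minus-strand elements need the gap on their 3'
        # genomic side (their 5' gene side); flip lead/trail handling
        if (el$truncation == "assembly_gap" && strand == "-") {
          lead <- sub(paste0(gap_run, "$"), "", lead)
          trail_gap <- gap_run
        } else trail_gap <- ""
        if (at_edge && strand == "-") {
          # 5'-truncated on minus strand belongs at the scaffold END;
          # simpler: force plus strand at the left edge
          strand <- "+"
          dna <- el$dna
        }
        need <- nchar(lead) + nchar(dna) + nchar(trail_gap)
        if (pos + need + 1000L > capacity)
          stop("genes exceed scaffold capacity; increase scaffold_len")
        pieces <- c(pieces, lead, dna, trail_gap)
        start <- pos + nchar(lead)
        pos <- pos + need
        truth[[length(truth) + 1L]] <- data.frame(
          element = sprintf("el%02d", i), scaffold = sprintf("scaf%d", s),
          start = start, end = start + nchar(dna), strand = strand,
          category = el$category, disruption = el$disruption,
          truncation = el$truncation, source = el$source,
          stringsAsFactors = FALSE)
      }
      tail_len <- capacity - pos
      if (tail_len > 0L) pieces <- c(pieces, random_dna(tail_len))
      scaffolds[s] <- paste(pieces, collapse = "")
    }
    names(scaffolds) <- sprintf("scaf%d", seq_len(n_sc))
    truth_df <- if (length(truth)) do.call(rbind, truth)
                else data.frame(element = character(0), scaffold = character(0),
                                start = integer(0), end = integer(0),
                                strand = character(0), category = character(0),
                                disruption = character(0),
                                truncation = character(0),
                                source = character(0), stringsAsFactors = FALSE)
    list(genome = genome_assembly(scaffolds), truth = truth_df)
  })
}
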