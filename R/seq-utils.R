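# Low-level sequence utilities shared by the mining and synthetic modules.
# DNA is handled as plain uppercase character strings over {A,C,G,T,N};
# Biostrings does the heavy lifting (translation, reverse complement).

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Validate a DNA string
#' @param seq character scalar
#' @param what label used in error messages
#' @return the sequence, invisibly
#' @keywords internal
check_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop(what, " must be a non-empty character scalar")
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad))
    stop(what, " contains characters outside {A,C,G,T,N}: ",
         substr(bad, 1, 10))
  invisible(seq)
}

#' Reverse complement of a DNA string
#' @param seq DNA string
#' @return character scalar
#' @export
dna_revcomp <- function(seq) {
  check_dna(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Translate a DNA string (standard code)
#'
#' Codons containing `N` translate to `X`; stop codons are rendered `*`.
#' Trailing bases that do not fill a codon are dropped.
#'
#' @param seq DNA string
#' @return amino-acid string (possibly empty when `nchar(seq) < 3`)
#' @export
translate_dna <- function(seq) {
  check_dna(seq)
  n <- nchar(seq) - nchar(seq) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(seq, 1L, n)),
    if.fuzzy.codon = "X", no.init.codon = TRUE))
}

#' Six-frame translation
#'
#' Translates the three forward frames and the three frames of the reverse
#' complement. Frame `k` (0-2) skips the first `k` bases of the
#' corresponding strand.
#'
#' @param seq DNA string over `{A,C,G,T,N}`
#' @return named list with elements `F0,F1,F2,R0,R1,R2` of amino-acid
#'   strings (stops as `*`, fuzzy codons as `X`)
#' @export
six_frame_translate <- function(seq) {
  check_dna(seq)
  rc <- dna_revcomp(seq)
  out <- c(
    lapply(0:2, function(k) translate_dna(substring(seq, k + 1L))),
    lapply(0:2, function(k) translate_dna(substring(rc, k + 1L))))
  names(out) <- c("F0", "F1", "F2", "R0", "R1", "R2")
  out
}

# Positions (1-based) of runs of >= min_run N's, as an IRanges-like matrix
# with columns start, end. Used for assembly-gap detection.
n_runs <- function(seq, min_run = 10L) {
  m <- gregexpr(sprintf("N{%d,}", min_run), seq)[[1]]
  if (m[1] == -1L) return(matrix(integer(0), ncol = 2,
                                 dimnames = list(NULL, c("start", "end"))))
  cbind(start = as.integer(m), end = as.integer(m) + attr(m, "match.length") - 1L)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Split an in-frame DNA string into codons (drops incomplete tail).
codons_of <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 3L
  if (n < 3L) return(character(0))
  substring(seq, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}

#' Construct a genome assembly object
#'
#' A thin validated container: named character vector of scaffold
#' sequences over `{A,C,G,T,N}` with unique ids.
#'
#' @param seqs named character vector (or named list) of DNA strings
#' @return object of class `genome_assembly`
#' @export
genome_assembly <- function(seqs) {
  seqs <- unlist(seqs)
  if (length(seqs) == 0L) stop("assembly must contain at least one scaffold")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)) ||
      any(!nzchar(names(seqs))))
    stop("scaffold ids must be present and unique")
  for (i in seq_along(seqs)) check_dna(seqs[[i]], names(seqs)[i])
  structure(list(seqs = seqs), class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("<genome_assembly> ", length(x$seqs), " scaffold(s), ",
      sum(nchar(x$seqs)), " nt total\n", sep = "")
  invisible(x)
}

#' Construct a query panel of protein sequences
#'
#' @param proteins named character vector of amino-acid strings
#'   (20-letter alphabet plus `X`)
#' @return object of class `query_panel`
#' @export
query_panel <- function(proteins) {
  proteins <- unlist(proteins)
  if (length(proteins) == 0L) stop("query panel must be non-empty")
  if (is.null(names(proteins)) || anyDuplicated(names(proteins)))
    stop("query ids must be present and unique")
  bad <- gsub("[ACDEFGHIKLMNPQRSTVWYX]", "", proteins)
  if (any(nzchar(bad)))
    stop("query proteins contain non-standard residues")
  structure(list(proteins = proteins), class = "query_panel")
}

#' @export
print.query_panel <- function(x, ...) {
  cat("<query_panel> ", length(x$proteins), " protein(s)\n", sep = "")
  invisible(x)
}

#' Read a genome assembly from FASTA
#' @param path FASTA file (gzipped allowed)
#' @return `genome_assembly`
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  genome_assembly(seqs)
}

#' Read a protein panel from FASTA
#' @param path FASTA file
#' @return `query_panel`
#' @export
read_panel_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  prot <- toupper(as.character(ss))
  names(prot) <- sub("\\s.*$", "", names(ss))
  query_panel(prot)
}

#' Write named sequences to FASTA
#' @param seqs named character vector
#' @param path output file
#' @param type `"dna"` or `"aa"`
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path, type = c("dna", "aa")) {
  type <- match.arg(type)
  ss <- if (type == "dna") Biostrings::DNAStringSet(unlist(seqs))
        else Biostrings::AAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
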