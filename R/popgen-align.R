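# Per-locus allele alignments with population labels. Missing data is
# handled by complete deletion: any column containing N or a gap is
# excluded from both the effective length and every statistic.

#' Construct a population alignment
#'
#' @param seqs named character vector of aligned allele sequences (equal
#'   length; `A,C,G,T` plus `N`/`-` for missing)
#' @param populations character vector of population labels, one per
#'   allele (each population must have at least 2 alleles)
#' @param locus locus id
#' @return object of class `pop_alignment` with fields `mat` (allele x
#'   site character matrix), `pop`, `locus`, `L` (alignment length) and
#'   `included` (logical: columns free of N/gaps)
#' @export
pop_alignment <- function(seqs, populations, locus = "locus") {
  seqs <- toupper(unlist(seqs))
  if (length(seqs) < 2L) stop("need at least 2 alleles")
  if (length(unique(nchar(seqs))) != 1L)
    stop("alleles must be aligned to equal length")
  if (length(populations) != length(seqs))
    stop("one population label per allele required")
  bad <- gsub("[ACGTN-]", "", seqs)
  if (any(nzchar(bad))) stop("alignment contains invalid characters")
  tb <- table(populations)
  if (any(tb < 2L)) stop("each population needs >= 2 alleles")
  if (is.null(names(seqs))) names(seqs) <- paste0("allele", seq_along(seqs))
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- names(seqs)
  included <- apply(mat, 2, function(col) !any(col %in% c("N", "-")))
  structure(list(mat = mat, pop = as.character(populations), locus = locus,
                 L = ncol(mat), included = included),
            class = "pop_alignment")
}

#' @export
print.pop_alignment <- function(x, ...) {
  cat(sprintf("<pop_alignment> %s: %d alleles x %d sites (%d included), pops: %s\n",
              x$locus, nrow(x$mat), x$L, sum(x$included),
              paste(sprintf("%s=%d", names(table(x$pop)), table(x$pop)),
                    collapse = ", ")))
  invisible(x)
}

#' Subset a population alignment to one population
#' @param aln `pop_alignment`
#' @param population label to keep
#' @return `pop_alignment` of that population only
#' @export
subset_population <- function(aln, population) {
  keep <- aln$pop == population
  if (sum(keep) < 2L) stop("population ", population, " has < 2 alleles")
  pop_alignment(apply(aln$mat[keep, , drop = FALSE], 1, paste, collapse = ""),
                aln$pop[keep], aln$locus)
}

#' Read a per-locus population alignment from multi-FASTA
#'
#' The population is taken from the allele id suffix after the last `|`
#' (e.g. `ind3_a2|chalk`), or from a two-column TSV map
#' (allele id, population).
#'
#' @param path FASTA file
#' @param popmap optional path to a headerless two-column TSV
#' @param locus locus id (defaults to the file name)
#' @return `pop_alignment`
#' @export
read_pop_fasta <- function(path, popmap = NULL, locus = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  ids <- sub("\\s.*$", "", names(ss))
  if (is.null(locus)) locus <- tools::file_path_sans_ext(basename(path))
  if (!is.null(popmap)) {
    pm <- utils::read.delim(popmap, header = FALSE, stringsAsFactors = FALSE)
    pops <- setNames(pm[[2]], pm[[1]])[ids]
    if (anyNA(pops)) stop("popmap does not cover all alleles")
  } else {
    if (!all(grepl("\\|", ids)))
      stop("allele ids must carry a '|population' suffix or use popmap=")
    pops <- sub("^.*\\|", "", ids)
    ids <- sub("\\|[^|]*$", "", ids)
  }
  names(seqs) <- ids
  pop_alignment(seqs, pops, locus)
}

#' Write a population alignment to multi-FASTA
#' @param aln `pop_alignment`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_pop_fasta <- function(aln, path) {
  seqs <- apply(aln$mat, 1, paste, collapse = "")
  names(seqs) <- paste0(rownames(aln$mat), "|", aln$pop)
  write_fasta(seqs, path, "dna")
}

# allele x site matrix restricted to included (complete) columns
included_mat <- function(aln) aln$mat[, aln$included, drop = FALSE]

# pairwise difference count matrix over included columns
pairwise_diffs <- function(aln) {
  m <- included_mat(aln)
  n <- nrow(m)
  d <- matrix(0, n, n)
  if (ncol(m) == 0L) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
    }
  }
  d
}
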