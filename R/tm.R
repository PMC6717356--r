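# Stand-in transmembrane-helix predictor: Kyte-Doolittle hydropathy with
# a 19-residue window. Replaces TMHMM/HMMTOP at desk scale; an adapter
# accepts externally produced topology strings instead.

KD_SCALE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Predict transmembrane helices by hydropathy
#'
#' Kyte-Doolittle sliding-window hydropathy (window 19, threshold 1.6 by
#' default). Windows whose mean hydropathy reaches the threshold are
#' merged when they overlap; each merged region is reported as one helix
#' of 19-25 residues (longer regions are trimmed around their
#' best-scoring window). Unknown residues (`X`) score 0.
#'
#' @param protein amino-acid string, length >= 100
#' @param window window width (residues)
#' @param threshold mean-hydropathy threshold
#' @param max_len maximum reported helix length
#' @return list with `count` and `spans` (data.frame `start`, `end`,
#'   1-based inclusive residue coordinates)
#' @export
predict_tm_helices <- function(protein, window = 19L, threshold = 1.6,
                               max_len = 25L) {
  if (!is.character(protein) || length(protein) != 1L)
    stop("protein must be a character scalar")
  protein <- sub("\\*$", "", protein)
  n <- nchar(protein)
  if (n < 100L) stop("protein too short for topology prediction (< 100 aa)")
  aa <- strsplit(protein, "")[[1]]
  h <- unname(KD_SCALE[aa])
  h[is.na(h)] <- 0
  cs <- cumsum(c(0, h))
  nw <- n - window + 1L
  means <- (cs[(window + 1L):(n + 1L)] - cs[1:nw]) / window
  hot <- which(means >= threshold)  # window start indices
  spans <- data.frame(start = integer(0), end = integer(0))
  if (length(hot)) {
    # merge overlapping hot windows: break where the next hot window
    # starts after the previous one ends
    brk <- c(0L, which(diff(hot) >= window), length(hot))
    for (k in seq_len(length(brk) - 1L)) {
      grp <- hot[(brk[k] + 1L):brk[k + 1L]]
      s <- min(grp); e <- max(grp) + window - 1L
      if (e - s + 1L > max_len) {
        best <- grp[which.max(means[grp])]
        mid <- best + (window - 1L) / 2
        s2 <- max(s, round(mid - (max_len - 1L) / 2))
        e2 <- min(e, s2 + max_len - 1L)
        s <- max(s, e2 - max_len + 1L); e <- e2
      }
      spans <- rbind(spans, data.frame(start = as.integer(s),
                                       end = as.integer(e)))
    }
  }
  list(count = nrow(spans), spans = spans)
}

#' Parse an externally produced topology string
#'
#' Adapter for TMHMM/HMMTOP-style per-residue topology strings using
#' `M`/`H` for membrane, `i`/`I` for inside and `o`/`O` for outside.
#'
#' @param topo per-residue topology string
#' @return list with `count` and `spans` as in [predict_tm_helices()]
#' @export
parse_topology_string <- function(topo) {
  stopifnot(is.character(topo), length(topo) == 1L, nzchar(topo))
  ch <- strsplit(topo, "")[[1]]
  inm <- ch %in% c("M", "H", "m", "h")
  r <- rle(inm)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  list(count = sum(keep),
       spans = data.frame(start = starts[keep], end = ends[keep]))
}
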