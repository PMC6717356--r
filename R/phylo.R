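# Phylogenetically independent contrasts (Felsenstein 1985) of gene
# counts and lifestyle codes on a dated species tree, and their Spearman
# rank correlation. Trees are ape "phylo" objects; the contrast algebra
# is implemented here (ape::pic serves as the independent oracle in the
# test suite).

#' Build a dated tree from a topology and node ages
#'
#' Branch lengths are `age(parent) - age(child)` with tip ages 0, so the
#' result is ultrametric in millions of years.
#'
#' @param topology a Newick string (internal nodes labelled) or a `phylo`
#'   object without branch lengths
#' @param node_ages named numeric: internal node label -> age (Myr)
#' @return `phylo` with branch lengths
#' @export
tree_from_node_ages <- function(topology, node_ages) {
  tree <- if (is.character(topology)) ape::read.tree(text = topology)
          else topology
  if (!inherits(tree, "phylo")) stop("topology must be Newick or phylo")
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label)))
    stop("all internal nodes must be labelled")
  missing <- setdiff(tree$node.label, names(node_ages))
  if (length(missing))
    stop("missing ages for nodes: ", paste(missing, collapse = ", "))
  ntip <- length(tree$tip.label)
  age_of <- function(node) {
    if (node <= ntip) 0 else unname(node_ages[tree$node.label[node - ntip]])
  }
  bl <- numeric(nrow(tree$edge))
  for (i in seq_len(nrow(tree$edge))) {
    bl[i] <- age_of(tree$edge[i, 1]) - age_of(tree$edge[i, 2])
    if (bl[i] <= 0)
      stop("non-positive branch length implied at edge ",
           tree$edge[i, 1], " -> ", tree$edge[i, 2],
           " (child age must be smaller than parent age)")
  }
  tree$edge.length <- bl
  tree
}

#' Phylogenetically independent contrasts
#'
#' Felsenstein's pruning algorithm: at each internal node with children
#' carrying values `x_i, x_j` on (adjusted) branch lengths `v_i, v_j`,
#' the standardized contrast is `(x_i - x_j) / sqrt(v_i + v_j)`, the
#' ancestral value is the precision-weighted mean, and the node's parent
#' branch is lengthened by `v_i v_j / (v_i + v_j)`. The sign convention
#' follows the child order of the tree (first child minus second); it is
#' irrelevant for correlations of contrasts as long as the same tree is
#' used for both traits.
#'
#' @param tree bifurcating `phylo` with positive branch lengths
#' @param values named numeric covering all tips
#' @return data.frame: `node` (internal node number), `contrast`
#' @export
compute_pics <- function(tree, values) {
  ntip <- length(tree$tip.label)
  if (!ape::is.binary(tree)) stop("tree must be fully bifurcating")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (!all(tree$tip.label %in% names(values)))
    stop("values must cover every tip")
  nnode <- tree$nNode %||% tree$Nnode
  x <- numeric(ntip + nnode)
  x[seq_len(ntip)] <- unname(values[tree$tip.label])
  # branch length above each node, adjustable during pruning
  vlen <- numeric(ntip + nnode)
  vlen[tree$edge[, 2]] <- tree$edge.length
  children <- split(tree$edge[, 2], tree$edge[, 1])
  contrast <- rep(NA_real_, nnode)
  done <- c(rep(TRUE, ntip), rep(FALSE, nnode))
  internal <- sort(as.integer(names(children)))
  repeat {
    todo <- internal[!done[internal]]
    if (!length(todo)) break
    progressed <- FALSE
    for (nd in todo) {
      ch <- children[[as.character(nd)]]
      if (length(ch) != 2L) stop("non-binary node ", nd)
      if (!all(done[ch])) next
      vi <- vlen[ch[1]]; vj <- vlen[ch[2]]
      contrast[nd - ntip] <- (x[ch[1]] - x[ch[2]]) / sqrt(vi + vj)
      x[nd] <- (x[ch[1]] / vi + x[ch[2]] / vj) / (1 / vi + 1 / vj)
      vlen[nd] <- vlen[nd] + vi * vj / (vi + vj)
      done[nd] <- TRUE
      progressed <- TRUE
    }
    if (!progressed) stop("tree traversal failed (cycle or disconnect)")
  }
  data.frame(node = internal, contrast = contrast[internal - ntip])
}

# exact two-tailed permutation p for Spearman's rho (opt-in, small n)
spearman_exact_p <- function(rx, ry) {
  n <- length(rx)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  rho_obs <- abs(stats::cor(rx, ry))
  all_p <- perms(seq_len(n))
  hits <- sum(vapply(all_p, function(idx)
    abs(stats::cor(rx, ry[idx])) >= rho_obs - 1e-12, logical(1)))
  hits / length(all_p)
}

#' Spearman rank correlation with two-tailed p
#'
#' rho is the Pearson correlation of mid-ranks (ties averaged); the
#' two-tailed p uses the t-approximation `t = rho * sqrt((n-2)/(1-rho^2))`
#' on `n - 2` degrees of freedom. An exact permutation p is available for
#' `n <= 10` via `exact = TRUE` (runtime grows factorially).
#'
#' @param x,y numeric vectors of equal length >= 3
#' @param exact use exhaustive permutation for the p-value (n <= 10)
#' @return list: `rho`, `p`, `n`, `method`
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  near_constant <- function(v)
    max(v) - min(v) <= 1e-10 * max(1, max(abs(v)))
  if (near_constant(x) || near_constant(y))
    stop("rho undefined: zero variance in ranks")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("rho undefined: zero variance in ranks")
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 10L) stop("exact permutation p limited to n <= 10")
    return(list(rho = rho, p = spearman_exact_p(rx, ry), n = n,
                method = "exact permutation"))
  }
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n, method = "t approximation")
}

#' Correlate repertoire size with lifestyle via contrasts
#'
#' Computes independent contrasts of the chosen gene count and of the
#' binary lifestyle code (0 = subterranean, 1 = superterranean, treated
#' as a continuous trait) on the same tree, then their Spearman
#' correlation. A through-origin least-squares slope of count contrasts
#' on lifestyle contrasts is reported as a secondary summary.
#'
#' @param tree dated bifurcating `phylo`
#' @param traits data.frame with columns `species`, `lifestyle` (0/1),
#'   `intact`, `functional`
#' @param which `"intact"` or `"functional"`
#' @return list: `rho`, `p`, `n`, `slope_through_origin`, `contrasts`
#'   (data.frame of the paired contrasts)
#' @export
lifestyle_correlation <- function(tree, traits, which = c("intact", "functional")) {
  which <- match.arg(which)
  need <- c("species", "lifestyle", which)
  if (!all(need %in% names(traits))) stop("traits must have columns ",
                                          paste(need, collapse = ", "))
  if (!setequal(traits$species, tree$tip.label))
    stop("trait species must match tree tips")
  if (!all(traits$lifestyle %in% c(0, 1)))
    stop("lifestyle codes must be 0 or 1")
  counts <- setNames(as.numeric(traits[[which]]), traits$species)
  codes <- setNames(as.numeric(traits$lifestyle), traits$species)
  pic_counts <- compute_pics(tree, counts)
  pic_codes <- compute_pics(tree, codes)
  sp <- spearman_cor(pic_codes$contrast, pic_counts$contrast)
  slope <- sum(pic_codes$contrast * pic_counts$contrast) /
    sum(pic_codes$contrast^2)
  list(rho = sp$rho, p = sp$p, n = sp$n, slope_through_origin = slope,
       contrasts = data.frame(node = pic_counts$node,
                              lifestyle = pic_codes$contrast,
                              count = pic_counts$contrast))
}
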