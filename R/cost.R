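## Empirical quintet topology distributions and the invariants+inequalities
## cost of a rooted quintet against such a distribution.

# column order of leaf pairs used by the vectorized topology classifier
.PAIRS5 <- combn(5L, 2L)
.PAIR_COL <- local({
  m <- matrix(0L, 5L, 5L)
  for (j in seq_len(ncol(.PAIRS5))) {
    m[.PAIRS5[1, j], .PAIRS5[2, j]] <- j
    m[.PAIRS5[2, j], .PAIRS5[1, j]] <- j
  }
  m
})

# topological (unit-branch-length) leaf-to-leaf distance matrix of one tree
.tip_distance_matrix <- function(tree) {
  ntip <- length(tree$tip.label)
  t2 <- tree
  t2$edge.length <- rep(1, nrow(t2$edge))
  D <- ape::dist.nodes(t2)[seq_len(ntip), seq_len(ntip)]
  dimnames(D) <- list(tree$tip.label, tree$tip.label)
  D
}

# Vectorized unrooted-quintet topology classification from pairwise
# topological distances.  `Dp` is a k x 10 matrix of distances among five
# leaves (columns in .PAIRS5 order, positions 1..5).  Returns an integer
# vector in 1..15, NA where the induced quintet is unresolved (distance
# ties, i.e. polytomies in the source tree).
.topology_from_pair_dists <- function(Dp) {
  k <- nrow(Dp)
  cherry <- matrix(TRUE, k, 10L)
  for (j in seq_len(10L)) {
    ij <- .PAIRS5[, j]
    rest <- setdiff(1:5, ij)
    quartets <- combn(rest, 2L)
    for (q in seq_len(ncol(quartets))) {
      kl <- quartets[, q]
      # four-point condition, strict: ties (polytomies) fail every pairing,
      # leaving fewer than two cherries, hence NA below
      s0 <- Dp[, j] + Dp[, .PAIR_COL[kl[1], kl[2]]]
      s1 <- Dp[, .PAIR_COL[ij[1], kl[1]]] + Dp[, .PAIR_COL[ij[2], kl[2]]]
      s2 <- Dp[, .PAIR_COL[ij[1], kl[2]]] + Dp[, .PAIR_COL[ij[2], kl[1]]]
      cherry[, j] <- cherry[, j] & (s0 < s1) & (s0 < s2)
    }
  }
  # a resolved (binary) quintet has exactly two disjoint cherries
  masks <- bitwShiftL(1L, .PAIRS5[1, ] - 1L) + bitwShiftL(1L, .PAIRS5[2, ] - 1L)
  lookup <- .qt()$pair_lookup
  out <- rep(NA_integer_, k)
  ok <- which(rowSums(cherry) == 2L)
  if (length(ok)) {
    ch <- apply(cherry[ok, , drop = FALSE], 1L, function(z) sort(masks[z]))
    out[ok] <- lookup[ch[1, ] * 32L + ch[2, ] + 1L]
  }
  out[out == 0L] <- NA_integer_
  out
}

# induced topology indices of many gene trees on one 5-taxon subset.
# `dists` is a list of tip-distance matrices (labels as dimnames);
# trees missing any of the taxa get NA.
.subset_topology_indices <- function(dists, taxa5) {
  taxa5 <- sort(taxa5)
  k <- length(dists)
  Dp <- matrix(NA_real_, k, 10L)
  has <- vapply(dists, function(D) all(taxa5 %in% rownames(D)), logical(1))
  for (g in which(has)) {
    D5 <- dists[[g]][taxa5, taxa5]
    Dp[g, ] <- D5[cbind(.PAIRS5[1, ], .PAIRS5[2, ])]
  }
  idx <- rep(NA_integer_, k)
  if (any(has)) idx[has] <- .topology_from_pair_dists(Dp[has, , drop = FALSE])
  attr(idx, "n_missing") <- sum(!has)
  idx
}

.new_quintet_freq <- function(counts, support, n_missing = 0L, n_unresolved = 0L,
                              taxa = NULL) {
  u <- if (support > 0L) counts / support else rep(0, 15L)
  structure(as.numeric(u), counts = as.integer(counts), support = as.integer(support),
            n_missing = as.integer(n_missing), n_unresolved = as.integer(n_unresolved),
            taxa = taxa, class = "quintet_freq")
}

#' Empirical distribution of unrooted quintet gene-tree topologies
#'
#' Restricts each gene tree to the five given taxa and tallies the induced
#' unrooted topology.  Gene trees missing any of the taxa, and gene trees
#' whose restriction is unresolved (polytomies), are excluded from both
#' numerator and denominator; their counts are recorded as attributes.
#'
#' @param gene_trees A `multiPhylo` (or list of `phylo`) of unrooted gene
#'   trees; rooted gene trees are used through their unrooted topology.
#' @param taxa Character vector of 5 leaf labels; positions 1..5 are the
#'   sorted labels.
#' @return A `quintet_freq`: numeric vector of 15 relative frequencies (in
#'   canonical topology order, summing to 1), with attributes `counts`,
#'   `support` (number of gene trees tallied), `n_missing`, `n_unresolved`
#'   and `taxa`.
#' @export
quintet_frequencies <- function(gene_trees, taxa) {
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  stopifnot(length(taxa) == 5L, !anyDuplicated(taxa))
  taxa <- sort(taxa)
  dists <- lapply(gene_trees, .tip_distance_matrix)
  idx <- .subset_topology_indices(dists, taxa)
  n_missing <- attr(idx, "n_missing")
  n_unres <- sum(is.na(idx)) - n_missing
  idx <- idx[!is.na(idx)]
  if (!length(idx))
    stop("empty quintet support: no gene tree resolves all of ",
         paste(taxa, collapse = ", "))
  counts <- tabulate(idx, nbins = 15L)
  .new_quintet_freq(counts, length(idx), n_missing, n_unres, taxa)
}

# distribution from precomputed topology indices (simulator fast path)
quintet_frequencies_from_indices <- function(idx) {
  idx <- idx[!is.na(idx)]
  if (!length(idx)) stop("empty quintet support")
  .new_quintet_freq(tabulate(idx, nbins = 15L), length(idx))
}

#' @export
print.quintet_freq <- function(x, ...) {
  cat(sprintf("quintet topology distribution (support %d gene trees",
              attr(x, "support")))
  if (attr(x, "n_missing") > 0L) cat(";", attr(x, "n_missing"), "missing taxa")
  if (attr(x, "n_unresolved") > 0L) cat(";", attr(x, "n_unresolved"), "unresolved")
  cat(")\n")
  v <- as.numeric(x)
  names(v) <- sprintf("t%d", 1:15)
  print(round(v, 4))
  invisible(x)
}

# validated numeric 15-vector from a quintet_freq or plain numeric
.as_u15 <- function(freq) {
  u <- as.numeric(freq)
  if (length(u) != 15L || any(u < 0) || anyNA(u))
    stop("distribution must be 15 nonnegative frequencies")
  s <- sum(u)
  if (s == 0) {
    support <- attr(freq, "support")
    if (!is.null(support) && support == 0L) return(u)
    stop("all-zero distribution with nonzero support")
  }
  if (abs(s - 1) > 1e-9)
    stop("distribution must be normalized (sums to ", format(s), ")")
  u
}

# flattened penalty-term index lists of one structure, cached per rooted id
.adr_terms <- function(id) {
  if (is.null(.qr_cache$terms)) .qr_cache$terms <- vector("list", 105L)
  tm <- .qr_cache$terms[[id]]
  if (!is.null(tm)) return(tm)
  st <- .adr_all()[[id]]
  inv_i <- integer(0); inv_j <- integer(0); inv_sz <- integer(0)
  for (cl in st$classes) {
    if (length(cl) < 2L) next
    pr <- combn(cl, 2L)
    inv_i <- c(inv_i, pr[1, ]); inv_j <- c(inv_j, pr[2, ])
    inv_sz <- c(inv_sz, rep(length(cl), ncol(pr)))
  }
  iq_hi <- integer(0); iq_lo <- integer(0); iq_losz <- integer(0)
  for (p in seq_len(nrow(st$order))) {
    hi <- st$classes[[st$order[p, 1]]]
    lo <- st$classes[[st$order[p, 2]]]
    grid <- expand.grid(hi = hi, lo = lo)
    iq_hi <- c(iq_hi, grid$hi); iq_lo <- c(iq_lo, grid$lo)
    iq_losz <- c(iq_losz, rep(length(lo), nrow(grid)))
  }
  # invariant sums run over ordered pairs (each |u_a - u_b| enters twice):
  # this is what makes the published weighted term counts (19/20/19) come
  # out as sum_c (|c|-1) + sum_{c>c'} |c|, and it reproduces the documented
  # category-bias behaviour of the unnormalized cost
  tm <- list(inv_i = inv_i, inv_j = inv_j, inv_w = 2 / inv_sz,
             iq_hi = iq_hi, iq_lo = iq_lo, iq_w = 1 / iq_losz)
  .qr_cache$terms[[id]] <- tm
  tm
}

#' Cost of a rooted quintet against a topology distribution
#'
#' Measures how strongly an (estimated) distribution of the 15 unrooted
#' quintet topologies violates the ADR invariants and inequalities of a
#' rooted quintet.  The production cost (variant 4) is
#' \deqn{\sum_{c} \frac{1}{|c|} \sum_{u_a, u_b \in c} |u_a - u_b| \;+\;
#'       \sum_{c>c'} \frac{1}{|c'|} \sum_{a \in c, b \in c'} \max(0, u_b - u_a),}
#' an absolute-difference penalty for every within-class pair (the double
#' sum runs over ordered pairs, so each pair enters twice -- the reading
#' under which the weighted penalty-term counts per shape are 19/20/19,
#' i.e. nearly equal) plus a hinge penalty for every reversed cross-class
#' pair, each class-normalized to remove the category bias that makes
#' unnormalized costs prefer some rooted shapes.  Variants: 1 = invariants
#' term only (normalized); 2 = both terms, unnormalized; 4 = the full
#' normalized cost.  Variant 3 (an alternative normalization) is not
#' available in this implementation and raises an error.
#'
#' @param freq A `quintet_freq` from [quintet_frequencies()], or a numeric
#'   vector of 15 nonnegative frequencies summing to 1 (canonical topology
#'   order).
#' @param rooted A rooted quintet id (1..105), vector of ids, shape name, or
#'   rooted binary 5-leaf `phylo`.
#' @param variant Cost variant: 1, 2 or 4 (default 4).
#' @param taxa Passed to [rooted_quintet_id()] when `rooted` is a tree.
#' @return Nonnegative cost value(s), one per element of `rooted`; zero iff
#'   the distribution satisfies all invariants and no inequality is strictly
#'   reversed.
#' @examples
#' u <- rep(1 / 15, 15)
#' quintet_cost(u, adr_structure("balanced")$id)  # 0: uniform satisfies all
#' @export
quintet_cost <- function(freq, rooted, variant = 4L, taxa = NULL) {
  u <- .as_u15(freq)
  if (is.character(rooted)) rooted <- .qt()$ref_ids[[match.arg(rooted, names(.ADR_BASE))]]
  if (inherits(rooted, "phylo")) rooted <- rooted_quintet_id(rooted, taxa)
  stopifnot(all(rooted %in% 1:105))
  if (!variant %in% c(1L, 2L, 4L)) {
    if (variant == 3L)
      stop("cost variant 3 (alternative normalization) is experimental and ",
           "not available in this implementation; use 1, 2 or 4")
    stop("unknown cost variant: ", variant)
  }
  vapply(rooted, function(id) {
    tm <- .adr_terms(id)
    inv_w <- if (variant == 2L) 2 else tm$inv_w
    iq_w <- if (variant == 2L) 1 else tm$iq_w
    val <- sum(inv_w * abs(u[tm$inv_i] - u[tm$inv_j]))
    if (variant != 1L)
      val <- val + sum(iq_w * pmax(0, u[tm$iq_lo] - u[tm$iq_hi]))
    val
  }, numeric(1))
}
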