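## Quintet-based rooting: score every candidate rooting of an unrooted
## species tree by the total invariants+inequalities cost of its induced
## rooted quintets against the empirical gene-tree topology distributions,
## and return the minimum-cost rooting.

.new_qr_rooting <- function(tree, rooted, candidates, tie, mode, variant,
                            n_subsets = 1L, n_skipped = 0L) {
  structure(list(tree = tree, rooted = rooted, candidates = candidates,
                 tie = tie, mode = mode, variant = variant,
                 n_subsets = n_subsets, n_skipped = n_skipped),
            class = "qr_rooting")
}

# argmin with deterministic tie-break on the lowest canonical edge id
.select_candidate <- function(scores, tol = 1e-12) {
  best <- min(scores)
  ties <- which(scores - best <= tol)
  list(sel = ties[1], tie = length(ties) > 1L)
}

#' Root a five-taxon tree from unrooted gene trees
#'
#' Tallies the empirical distribution of the 15 unrooted quintet gene-tree
#' topologies, scores all 7 rootings of the species tree with the chosen
#' cost variant, and returns the minimum-cost rooting (ties broken towards
#' the lowest canonical edge id and flagged).
#'
#' @param tree Unrooted binary `phylo` on 5 taxa (a rooted input is used
#'   through its unrooted topology).
#' @param gene_trees `multiPhylo` of gene trees, each containing all 5 taxa
#'   (trees missing taxa are excluded from the tally).  Ignored when `freq`
#'   is given.
#' @param freq Optional precomputed [quintet_frequencies()] distribution.
#' @param variant Cost variant (1, 2 or 4; see [quintet_cost()]).
#' @return A `qr_rooting` object: `$rooted` is the selected rooted tree,
#'   `$candidates` a data.frame of per-edge scores, `$tie` the tie flag.
#' @examples
#' sp <- quintet_model_tree("caterpillar", internal = 0.5)
#' gts <- sim_gene_trees(sp, 200, seed = 7)
#' root_quintet(ape::unroot(sp), gts)
#' @export
root_quintet <- function(tree, gene_trees = NULL, freq = NULL, variant = 4L) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) != 5L)
    stop("root_quintet needs exactly 5 taxa; see root_species_tree()")
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  if (tree$Nnode != 3L) stop("species tree must be binary")
  if (is.null(freq)) {
    if (is.null(gene_trees)) stop("supply gene_trees or freq")
    freq <- quintet_frequencies(gene_trees, tree$tip.label)
  }
  ed <- tree_edges(tree)
  stopifnot(nrow(ed) == 7L)
  rooted_trees <- lapply(ed$edge, function(e) reroot_on_edge(tree, e))
  ids <- vapply(rooted_trees, rooted_quintet_id, integer(1))
  scores <- quintet_cost(freq, ids, variant = variant)
  pick <- .select_candidate(scores)
  cand <- data.frame(edge = ed$edge, split = ed$split, rooted_id = ids,
                     score = scores, stringsAsFactors = FALSE)
  .new_qr_rooting(tree, rooted_trees[[pick$sel]], cand, pick$tie,
                  mode = "quintet", variant = variant)
}

# tip sets of the four subtrees hanging off an internal edge, plus helpers
.component_tips <- function(adj, ntip, start, blocked) {
  seen <- c(start); frontier <- start
  while (length(frontier)) {
    nxt <- setdiff(unlist(adj[frontier]), c(seen, blocked))
    seen <- c(seen, nxt); frontier <- nxt
  }
  seen[seen <= ntip]
}

# O(n) quintet selection ("edge-spanning" strategy): for each internal edge,
# the nearest leaf in each of the four subtrees it separates, plus the
# nearest remaining fifth leaf; deterministic tie-breaks by label
.linear_subsets <- function(tree) {
  ntip <- length(tree$tip.label)
  t2 <- tree; t2$edge.length <- rep(1, nrow(t2$edge))
  Dn <- ape::dist.nodes(t2)
  adj <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(nrow(tree$edge))) {
    a <- tree$edge[i, 1]; b <- tree$edge[i, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  lab <- tree$tip.label
  nearest <- function(tips, node) {
    d <- Dn[node, tips]
    cand <- tips[d == min(d)]
    cand[order(lab[cand])][1]
  }
  internal <- which(tree$edge[, 1] > ntip & tree$edge[, 2] > ntip)
  subsets <- list()
  for (i in internal) {
    u <- tree$edge[i, 1]; v <- tree$edge[i, 2]
    picks <- integer(0)
    for (w in setdiff(adj[[u]], v))
      picks <- c(picks, nearest(.component_tips(adj, ntip, w, u), u))
    for (w in setdiff(adj[[v]], u))
      picks <- c(picks, nearest(.component_tips(adj, ntip, w, v), v))
    rest <- setdiff(seq_len(ntip), picks)
    d5 <- pmin(Dn[u, rest], Dn[v, rest])
    cand <- rest[d5 == min(d5)]
    fifth <- cand[order(lab[cand])][1]
    subsets[[length(subsets) + 1L]] <- sort(lab[c(picks, fifth)])
  }
  unique(subsets)
}

#' Root a species tree from unrooted gene trees
#'
#' Scores each of the 2n-3 candidate rootings of an unrooted n-taxon species
#' tree as the sum, over a set Q* of five-taxon subsets, of the cost of the
#' candidate's induced rooted quintet against the empirical gene-tree
#' topology distribution on that subset; the minimum-cost rooting is
#' returned.  `mode = "all"` uses every five-taxon subset (Theta(n^5)
#' quintets, most informative); `mode = "linear"` uses O(n) subsets chosen
#' by the edge-spanning strategy (one quintet per internal edge, spanning
#' its four subtrees plus the nearest fifth leaf), which is much faster on
#' large trees but somewhat less accurate.  Subsets with no gene-tree
#' support are skipped and counted in the result.
#'
#' @param tree Unrooted binary `phylo` on n >= 5 taxa (a rooted input is
#'   used through its unrooted topology).
#' @param gene_trees `multiPhylo` of unrooted gene trees on (subsets of) the
#'   species taxa.
#' @param mode `"all"` or `"linear"`.
#' @param variant Cost variant (1, 2 or 4; see [quintet_cost()]).
#' @return A `qr_rooting` object (see [root_quintet()]); `$n_subsets` and
#'   `$n_skipped` summarize the quintet subsets used.
#' @export
root_species_tree <- function(tree, gene_trees, mode = c("all", "linear"),
                              variant = 4L) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n < 5L) stop("species tree must have at least 5 taxa")
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  if (!ape::is.binary(tree)) stop("species tree must be binary")
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  taxa <- sort(tree$tip.label)

  # candidate rootings and their nontrivial clades as position masks
  ed <- tree_edges(tree)
  stopifnot(nrow(ed) == 2L * n - 3L)
  rooted_trees <- lapply(ed$edge, function(e) reroot_on_edge(tree, e))
  cand_clades <- lapply(rooted_trees, function(rt) {
    root <- length(rt$tip.label) + 1L
    nodes <- setdiff(unique(rt$edge[, 1]), root)
    m <- matrix(FALSE, length(nodes), n)
    for (j in seq_along(nodes)) {
      tips <- rt$tip.label[unlist(phangorn::Descendants(rt, nodes[j], "tips"))]
      m[j, match(tips, taxa)] <- TRUE
    }
    m
  })

  # per-gene-tree topological distances over all taxon pairs
  dists <- lapply(gene_trees, .tip_distance_matrix)
  k <- length(dists)
  npair <- n * (n - 1L) / 2L
  PCOL <- matrix(0L, n, n); cnt <- 0L
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    cnt <- cnt + 1L; PCOL[i, j] <- cnt; PCOL[j, i] <- cnt
  }
  Dall <- matrix(NA_real_, k, npair)
  for (g in seq_len(k)) {
    pos <- match(rownames(dists[[g]]), taxa)
    keep <- !is.na(pos)
    if (sum(keep) < 2L) next
    D <- dists[[g]][keep, keep, drop = FALSE]
    p <- pos[keep]
    for (a in seq_along(p)) for (b in seq_along(p)) {
      if (a < b) Dall[g, PCOL[p[a], p[b]]] <- D[a, b]
    }
  }

  subsets <-
    if (mode == "all") {
      m <- combn(n, 5L)
      lapply(seq_len(ncol(m)), function(j) m[, j])
    } else {
      lapply(.linear_subsets(tree), function(s) match(s, taxa))
    }

  pow2 <- 2^(0:4)
  scores <- numeric(nrow(ed))
  n_skipped <- 0L
  for (q in subsets) {
    cols <- PCOL[cbind(q[.PAIRS5[1, ]], q[.PAIRS5[2, ]])]
    Dp <- Dall[, cols, drop = FALSE]
    has <- !rowSums(is.na(Dp))
    if (!any(has)) { n_skipped <- n_skipped + 1L; next }
    idx <- .topology_from_pair_dists(Dp[has, , drop = FALSE])
    idx <- idx[!is.na(idx)]
    if (!length(idx)) { n_skipped <- n_skipped + 1L; next }
    u <- tabulate(idx, nbins = 15L) / length(idx)
    ids <- vapply(cand_clades, function(cm) {
      sub <- cm[, q, drop = FALSE]
      sz <- rowSums(sub)
      keep <- sz >= 2L & sz <= 4L
      masks <- unique(as.integer(sub[keep, , drop = FALSE] %*% pow2))
      .rooted_id_from_masks(masks)
    }, integer(1))
    uniq <- unique(ids)
    cost_by_id <- quintet_cost(u, uniq, variant = variant)
    scores <- scores + cost_by_id[match(ids, uniq)]
  }
  if (n_skipped == length(subsets))
    stop("no five-taxon subset has gene-tree support")

  pick <- .select_candidate(scores)
  cand <- data.frame(edge = ed$edge, split = ed$split, score = scores,
                     stringsAsFactors = FALSE)
  .new_qr_rooting(tree, rooted_trees[[pick$sel]], cand, pick$tie,
                  mode = mode, variant = variant,
                  n_subsets = length(subsets) - n_skipped,
                  n_skipped = n_skipped)
}

#' @export
print.qr_rooting <- function(x, ...) {
  n <- length(x$tree$tip.label)
  cat(sprintf("quintet rooting (%d taxa, mode %s, cost variant %d)\n",
              n, x$mode, x$variant))
  if (x$mode != "quintet")
    cat(sprintf("  quintet subsets used: %d (skipped: %d)\n",
                x$n_subsets, x$n_skipped))
  sel <- x$candidates$edge[which.min(x$candidates$score)]
  cat(sprintf("  candidates scored: %d; selected edge %d (score %.6g)%s\n",
              nrow(x$candidates), sel, min(x$candidates$score),
              if (x$tie) " [tie]" else ""))
  cat("  rooted tree:", ape::write.tree(x$rooted), "\n")
  invisible(x)
}

#' @export
plot.qr_rooting <- function(x, ...) {
  ape::plot.phylo(x$rooted, ...)
  invisible(x)
}
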