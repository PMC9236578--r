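## Multi-species-coalescent gene-tree simulator.
##
## Gene trees are generated inside a rooted model species tree whose internal
## branch lengths are in coalescent units (CU): one lineage enters at each
## tip; within a species-tree branch of length t carrying m lineages, the
## next coalescence occurs after an Exp(m(m-1)/2) waiting time and merges a
## uniformly chosen pair; lineages surviving to the root coalesce there
## until one remains (the root branch is effectively infinite).  Pendant
## branch lengths do not affect the topology distribution; they only shift
## node heights.

# preprocessed species-tree description for the simulator
.sim_prep <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("model species tree must be rooted")
  if (!ape::is.binary(tree)) stop("model species tree must be binary")
  ntip <- length(tree$tip.label)
  if (is.null(tree$edge.length)) stop("model species tree needs branch lengths (coalescent units)")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("branch lengths must be nonnegative coalescent units")
  internal_child <- tree$edge[, 2] > ntip
  if (any(tree$edge.length[internal_child] <= 0))
    stop("internal branch lengths must be positive coalescent units")
  nnode <- ntip + tree$Nnode
  parent <- integer(nnode); blen <- numeric(nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  blen[tree$edge[, 2]] <- tree$edge.length
  root <- ntip + 1L
  blen[root] <- Inf
  # depth of each node from the root (for absolute coalescent times)
  depth <- numeric(nnode)
  pre <- rev(ape::postorder(tree))
  for (i in pre) {
    ch <- tree$edge[i, 2]
    depth[ch] <- depth[tree$edge[i, 1]] + tree$edge.length[i]
  }
  # children of each internal node
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  # children-before-parents order: internal branch lengths are positive, so
  # sorting internal nodes by decreasing depth is a valid postorder
  internal <- seq.int(ntip + 1L, nnode)
  post <- internal[order(depth[internal], decreasing = TRUE)]
  pairs <- lapply(seq_len(ntip), function(m) if (m >= 2) combn(m, 2L) else NULL)
  list(tree = tree, ntip = ntip, parent = parent, blen = blen, depth = depth,
       kids = kids, post = post, root = root, pairs = pairs,
       labels = tree$tip.label)
}

# simulate one gene tree; returns merge records.  `masks` tracks 5-bit
# cluster masks when tip_pos is given (quintet fast path).
.sim_one <- function(prep, tip_pos = NULL) {
  ntip <- prep$ntip
  n_gnode <- 2L * ntip - 1L
  gparent <- integer(n_gnode)
  gheight <- numeric(n_gnode)
  gheight[seq_len(ntip)] <- -prep$depth[seq_len(ntip)]
  masks <- if (!is.null(tip_pos)) c(bitwShiftL(1L, tip_pos - 1L), integer(ntip - 1L))
  nxt <- ntip + 1L
  lin_at <- vector("list", ntip + prep$tree$Nnode)
  for (i in seq_len(ntip)) lin_at[[i]] <- i
  for (nd in c(prep$post)) {
    lins <- unlist(lin_at[prep$kids[[as.character(nd)]]], use.names = FALSE)
    tlim <- prep$blen[nd]
    u <- -prep$depth[nd]
    m <- length(lins)
    while (m > 1L) {
      w <- rexp(1L, m * (m - 1L) / 2)
      if (u + w - (-prep$depth[nd]) > tlim) break
      u <- u + w
      pr <- prep$pairs[[m]]
      j <- 1L + min(floor(runif(1L) * ncol(pr)), ncol(pr) - 1L)
      i1 <- lins[pr[1L, j]]; i2 <- lins[pr[2L, j]]
      gparent[i1] <- nxt; gparent[i2] <- nxt
      gheight[nxt] <- u
      if (!is.null(masks)) masks[nxt] <- bitwOr(masks[i1], masks[i2])
      lins <- c(lins[-c(pr[1L, j], pr[2L, j])], nxt)
      nxt <- nxt + 1L
      m <- m - 1L
    }
    lin_at[[nd]] <- lins
  }
  list(gparent = gparent, gheight = gheight, masks = masks, n_gnode = nxt - 1L)
}

# convert merge records to a rooted phylo with CU branch lengths;
# internal nodes renumbered in preorder (ape cladewise convention)
.sim_as_phylo <- function(rec, labels) {
  ntip <- length(labels)
  n <- rec$n_gnode
  par <- rec$gparent
  kids <- vector("list", n)
  for (ch in seq_len(n)) if (par[ch] > 0L) kids[[par[ch]]] <- c(kids[[par[ch]]], ch)
  root_old <- n                     # the final merge is the gene-tree root
  ord <- integer(n); np <- 0L
  stack <- root_old
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    np <- np + 1L; ord[np] <- nd
    stack <- c(stack, rev(kids[[nd]]))
  }
  newid <- integer(n)
  newid[seq_len(ntip)] <- seq_len(ntip)
  internal <- ord[ord > ntip]
  newid[internal] <- ntip + seq_along(internal)
  nonroot <- ord[ord != root_old]
  edge <- cbind(newid[par[nonroot]], newid[nonroot])
  elen <- rec$gheight[par[nonroot]] - rec$gheight[nonroot]
  phy <- list(edge = edge, edge.length = elen, Nnode = n - ntip,
              tip.label = labels)
  class(phy) <- "phylo"
  attr(phy, "order") <- "cladewise"
  phy
}

#' Simulate gene trees under the multi-species coalescent
#'
#' @param species_tree Rooted binary `phylo` with branch lengths in
#'   coalescent units (internal branches must be positive).
#' @param k Number of gene trees.
#' @param seed Optional integer seed (one seeded generator per call; genes
#'   are drawn sequentially from it).
#' @param unrooted Return gene trees unrooted (the default; rooting-by-
#'   quintets consumes unrooted topologies only).  Branch lengths are kept.
#' @return A `multiPhylo` of `k` gene trees.
#' @examples
#' sp <- quintet_model_tree("caterpillar", internal = 0.5)
#' gts <- sim_gene_trees(sp, 20, seed = 1)
#' @export
sim_gene_trees <- function(species_tree, k, seed = NULL, unrooted = TRUE) {
  stopifnot(k >= 1L)
  if (!is.null(seed)) set.seed(seed)
  prep <- .sim_prep(species_tree)
  out <- vector("list", k)
  for (g in seq_len(k)) {
    phy <- .sim_as_phylo(.sim_one(prep), prep$labels)
    out[[g]] <- if (unrooted) ape::unroot(phy) else phy
  }
  class(out) <- "multiPhylo"
  out
}

#' Simulate quintet gene-tree topology indices
#'
#' Fast path for five-taxon model trees: simulates gene trees under the MSC
#' exactly as [sim_gene_trees()] (identical random stream) but returns only
#' the canonical unrooted topology index of each gene tree.
#'
#' @inheritParams sim_gene_trees
#' @param species_tree Rooted binary 5-taxon `phylo` with CU branch lengths.
#' @return Integer vector of length `k` with values in 1..15 (taxa mapped to
#'   positions 1..5 by sorted label order).
#' @export
sim_quintet_indices <- function(species_tree, k, seed = NULL) {
  stopifnot(length(species_tree$tip.label) == 5L, k >= 1L)
  if (!is.null(seed)) set.seed(seed)
  prep <- .sim_prep(species_tree)
  tip_pos <- match(prep$labels, sort(prep$labels))
  lookup <- .qt()$pair_lookup
  idx <- integer(k)
  for (g in seq_len(k)) {
    rec <- .sim_one(prep, tip_pos = tip_pos)
    msk <- rec$masks[6:9]
    sz <- .POPCNT5[msk + 1L]
    # unrooted cherries of a rooted quintet: its 2-clades plus the
    # complements of its 3-clades
    cherries <- c(msk[sz == 2L], bitwAnd(bitwNot(msk[sz == 3L]), 31L))
    cherries <- sort(unique(cherries))
    stopifnot(length(cherries) == 2L)
    idx[g] <- lookup[cherries[1] * 32L + cherries[2] + 1L]
  }
  idx
}

#' Perturb gene-tree branch lengths away from a molecular clock
#'
#' Multiplies every branch length by an i.i.d. lognormal factor with log-sd
#' `sigma` (mean factor `exp(sigma^2/2)`).  Topologies are unchanged, so
#' quintet-based rooting is unaffected by this perturbation.
#'
#' @param trees `phylo` or `multiPhylo` with branch lengths.
#' @param sigma Lognormal log-sd; `0` is the identity.
#' @param seed Optional integer seed.
#' @return Trees with perturbed branch lengths.
#' @export
perturb_clock <- function(trees, sigma, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  single <- inherits(trees, "phylo")
  if (single) { trees <- list(trees); class(trees) <- "multiPhylo" }
  for (i in seq_along(trees)) {
    if (is.null(trees[[i]]$edge.length)) stop("tree ", i, " has no branch lengths")
    ne <- length(trees[[i]]$edge.length)
    trees[[i]]$edge.length <- trees[[i]]$edge.length * rlnorm(ne, 0, sigma)
  }
  if (single) trees[[1]] else trees
}

#' Perturb gene-tree topologies with random NNI moves
#'
#' Desk-scale stand-in for gene-tree estimation error: with probability
#' `prob`, a tree receives `moves` random nearest-neighbour-interchange
#' rearrangements (via `phangorn::rNNI`).
#'
#' @param trees `multiPhylo`.
#' @param prob Per-tree perturbation probability.
#' @param moves NNI moves applied to a perturbed tree.
#' @param seed Optional integer seed.
#' @return Perturbed `multiPhylo`.
#' @export
perturb_nni <- function(trees, prob, moves = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(prob >= 0, prob <= 1)
  for (i in seq_along(trees)) {
    if (runif(1) < prob) trees[[i]] <- phangorn::rNNI(trees[[i]], moves = moves)
  }
  trees
}

#' Build a rooted quintet model species tree with CU branch lengths
#'
#' @param x Rooted quintet id (1..105) or shape name (uses the shape's
#'   reference topology).
#' @param internal Internal branch lengths in coalescent units (scalar or
#'   length 3, recycled in the tree's internal-edge order).
#' @param terminal Pendant branch length (does not affect topology
#'   probabilities).
#' @param labels Leaf labels for positions 1..5.
#' @return Rooted binary `phylo` with branch lengths.
#' @export
quintet_model_tree <- function(x, internal = 0.5, terminal = 1,
                               labels = letters[1:5]) {
  if (is.character(x)) x <- .qt()$ref_ids[[match.arg(x, names(.ADR_BASE))]]
  phy <- ape::read.tree(text = rooted_quintet_newick(x, labels))
  ntip <- 5L
  internal_edge <- phy$edge[, 2] > ntip
  len <- rep(terminal, nrow(phy$edge))
  len[internal_edge] <- rep_len(internal, sum(internal_edge))
  phy$edge.length <- len
  phy
}

#' Random rooted model species tree for simulation studies
#'
#' Uniform random rooted binary topology (via `ape::rtree`) with internal
#' branch lengths drawn uniformly from `internal_range` (coalescent units)
#' and constant pendant lengths.
#'
#' @param n Number of taxa.
#' @param internal_range Range for internal branch lengths (CU).
#' @param terminal Pendant branch length (CU).
#' @param labels Optional leaf labels (default `t1..tn`).
#' @return Rooted binary `phylo` with branch lengths.
#' @export
random_model_tree <- function(n, internal_range = c(0.2, 1), terminal = 1,
                              labels = NULL) {
  phy <- ape::rtree(n, rooted = TRUE, br = NULL)
  if (!is.null(labels)) phy$tip.label <- labels else
    phy$tip.label <- sprintf("t%02d", seq_len(n))
  internal_edge <- phy$edge[, 2] > n
  len <- rep(terminal, nrow(phy$edge))
  len[internal_edge] <- runif(sum(internal_edge), internal_range[1], internal_range[2])
  phy$edge.length <- len
  phy
}
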