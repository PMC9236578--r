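## Evaluation metrics for rooted and unrooted trees: normalized clade
## distance, root distance, normalized Robinson-Foulds bipartition distance,
## average discordance (ILS level) and the proportion of correct rootings.

# nontrivial clades of a rooted tree as sorted-label signatures
.clade_signatures <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nodes <- setdiff(unique(tree$edge[, 1]), root)
  vapply(nodes, function(nd) {
    tips <- tree$tip.label[unlist(phangorn::Descendants(tree, nd, "tips"))]
    paste(sort(tips), collapse = "|")
  }, "")
}

#' Normalized clade distance between two rooted trees
#'
#' The rooted analogue of the Robinson-Foulds error rate: the size of the
#' symmetric difference of the two trees' nontrivial clade sets, divided by
#' `2n - 4` (a binary rooted tree on n leaves has `n - 2` nontrivial
#' clades).  Two rootings of the same unrooted binary topology differ only
#' near the root, and their clade distance is twice their root distance.
#'
#' @param tree,ref Rooted binary `phylo` objects on the same leaf set
#'   (n >= 3).
#' @return List of class `clade_distance` with `numerator` (symmetric
#'   difference count), `denominator` (`2n - 4`) and `normalized`
#'   (in `[0, 1]`).
#' @examples
#' t1 <- read_trees("((((a,b),c),d),e);")[[1]]
#' t2 <- read_trees("((((b,c),a),d),e);")[[1]]
#' clade_distance(t1, t2)$normalized
#' @export
clade_distance <- function(tree, ref) {
  if (!setequal(tree$tip.label, ref$tip.label))
    stop("trees have different leaf sets")
  n <- length(tree$tip.label)
  a <- .clade_signatures(tree); b <- .clade_signatures(ref)
  num <- length(setdiff(a, b)) + length(setdiff(b, a))
  den <- 2L * n - 4L
  structure(list(numerator = num, denominator = den, normalized = num / den),
            class = "clade_distance")
}

#' @export
print.clade_distance <- function(x, ...) {
  cat(sprintf("clade distance: %d/%d = %.4f\n",
              x$numerator, x$denominator, x$normalized))
  invisible(x)
}

# canonical far-side signature of the rooting edge of rooted tree T inside
# unrooted tree t; errors if T is not a rooting of t
.root_edge_of <- function(t, rooted) {
  root <- length(rooted$tip.label) + 1L
  kids <- rooted$edge[rooted$edge[, 1] == root, 2]
  if (length(kids) != 2L) stop("tree is not rooted (degree-2 root expected)")
  side <- unlist(phangorn::Descendants(rooted, kids[1], "tips"))
  side <- sort(rooted$tip.label[side])
  anchor <- min(t$tip.label)
  sig <- if (anchor %in% side)
    paste(sort(setdiff(t$tip.label, side)), collapse = "|")
  else paste(side, collapse = "|")
  ed <- tree_edges(t)
  hit <- ed$edge[ed$split == sig]
  if (!length(hit)) stop("rooted tree is not a rooting of the unrooted tree")
  # also require identical unrooted topologies, not just a matching edge
  ru <- ape::unroot(rooted)
  if (!setequal(tree_edges(ru)$split, ed$split))
    stop("rooted tree is not a rooting of the unrooted tree")
  hit[1]
}

#' Root distance between two rootings of an unrooted tree
#'
#' Number of edges of the unrooted topology `t` separating the rooting edge
#' of `tree` from that of `ref` (0 when both root the same edge, 1 for
#' adjacent edges).  Also checks the identity that the clade-distance
#' numerator equals twice the root distance.
#'
#' @param t Unrooted binary `phylo`.
#' @param tree,ref Rooted trees whose unrooted topology is `t`.
#' @return Integer edge count.
#' @export
root_distance <- function(t, tree, ref) {
  if (ape::is.rooted(t)) stop("`t` must be unrooted")
  e1 <- .root_edge_of(t, tree); e2 <- .root_edge_of(t, ref)
  if (e1 == e2) rd <- 0L else {
    ed <- tree_edges(t)
    t2 <- t; t2$edge.length <- rep(1, nrow(t2$edge))
    Dn <- ape::dist.nodes(t2)
    ends1 <- t$edge[ed$row[ed$edge == e1], ]
    ends2 <- t$edge[ed$row[ed$edge == e2], ]
    rd <- as.integer(min(Dn[ends1, ends2]) + 1L)
  }
  cd <- clade_distance(tree, ref)
  stopifnot(cd$numerator == 2L * rd)
  rd
}

#' Normalized Robinson-Foulds distance between two unrooted trees
#'
#' Bipartition symmetric-difference count divided by its maximum
#' `2(n - 3)`; rooted inputs are compared through their unrooted topologies.
#'
#' @param t1,t2 `phylo` objects on the same leaf set.
#' @return Value in `[0, 1]`.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  if (ape::is.rooted(t1)) t1 <- ape::unroot(t1)
  if (ape::is.rooted(t2)) t2 <- ape::unroot(t2)
  as.numeric(phangorn::RF.dist(t1, t2, normalize = TRUE, check.labels = TRUE))
}

#' Average discordance between a species tree and gene trees
#'
#' Mean normalized RF bipartition distance between the species tree and each
#' gene tree (each comparison restricted to the shared taxa); the standard
#' summary of ILS level (AD).  Gene trees sharing fewer than 4 taxa with the
#' species tree carry no bipartition information and are skipped.
#'
#' @param species_tree `phylo`.
#' @param gene_trees `multiPhylo` or list of `phylo`.
#' @return Mean normalized RF distance.
#' @export
average_discordance <- function(species_tree, gene_trees) {
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  vals <- vapply(gene_trees, function(gt) {
    common <- intersect(species_tree$tip.label, gt$tip.label)
    if (length(common) < 4L) return(NA_real_)
    rf_distance(restrict_tree(species_tree, common),
                restrict_tree(gt, common))
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Proportion of correctly rooted trees
#'
#' Fraction of estimated rooted trees at clade distance 0 from their
#' reference rooted tree.
#'
#' @param estimated List of rooted `phylo` (or a single one).
#' @param ref A rooted `phylo`, or a list of the same length as `estimated`.
#' @return Fraction in `[0, 1]`.
#' @export
proportion_correct <- function(estimated, ref) {
  if (inherits(estimated, "phylo")) estimated <- list(estimated)
  if (inherits(ref, "phylo")) ref <- rep(list(ref), length(estimated))
  stopifnot(length(ref) == length(estimated))
  mean(vapply(seq_along(estimated), function(i)
    clade_distance(estimated[[i]], ref[[i]])$normalized == 0, logical(1)))
}
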