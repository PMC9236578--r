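## Catalogue of the 15 unrooted and 105 rooted five-taxon (quintet) topologies,
## canonical indexing, shape classification, and the S5 leaf-relabeling action.
##
## Internal convention: the five taxa of a quintet are mapped onto positions
## 1..5 (printed as a..e).  An unrooted binary quintet is two disjoint cherry
## pairs plus a lone leaf; the canonical index 1..15 is the lexicographic rank
## of the sorted pair of cherries.  A rooted quintet is (topology, root edge)
## with edges 1..5 the pendant edges (by leaf) and 6, 7 the internal edges
## adjacent to the first and second cherry; its id is (topology - 1) * 7 + edge.

# number of set bits for masks 0..31
.POPCNT5 <- vapply(0:31, function(m) sum(bitwAnd(m, 2L^(0:4)) > 0L), integer(1))

.mask <- function(leaves) as.integer(sum(bitwShiftL(1L, leaves - 1L)))
.unmask <- function(m) which(bitwAnd(m, 2L^(0:4)) > 0L)

# all permutations of 1:5 in lexicographic order (120 x 5)
.perms5 <- function() {
  rec <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1L, 1L))
    do.call(rbind, lapply(seq_along(v), function(i) {
      cbind(v[i], rec(v[-i]), deparse.level = 0)
    }))
  }
  rec(1:5)
}

# lazily build and cache the quintet lookup tables
.qt <- function() {
  if (!is.null(.qr_cache$qt)) return(.qr_cache$qt)
  pairs2 <- combn(5L, 2L)                      # 2-subsets in lex order
  tp <- list(); lone <- integer(0)
  for (i in seq_len(ncol(pairs2))) {
    for (j in seq_len(ncol(pairs2))) {
      p1 <- pairs2[, i]; p2 <- pairs2[, j]
      if (i < j && length(intersect(p1, p2)) == 0L) {
        tp[[length(tp) + 1L]] <- c(p1, p2)
        lone <- c(lone, setdiff(1:5, c(p1, p2)))
      }
    }
  }
  qt_pairs <- do.call(rbind, tp)               # 15 x 4: p1a p1b p2a p2b
  stopifnot(nrow(qt_pairs) == 15L)

  # topology index from the two cherry masks
  pair_lookup <- integer(32L * 32L)
  for (t in 1:15) {
    m1 <- .mask(qt_pairs[t, 1:2]); m2 <- .mask(qt_pairs[t, 3:4])
    pair_lookup[min(m1, m2) * 32L + max(m1, m2) + 1L] <- t
  }

  perms <- .perms5()
  perm_key <- apply(perms, 1L, paste, collapse = "")

  # action of each permutation on topology indices
  topo_action <- matrix(0L, 120L, 15L)
  for (s in 1:120) {
    sig <- perms[s, ]
    for (t in 1:15) {
      m1 <- .mask(sig[qt_pairs[t, 1:2]]); m2 <- .mask(sig[qt_pairs[t, 3:4]])
      topo_action[s, t] <- pair_lookup[min(m1, m2) * 32L + max(m1, m2) + 1L]
    }
  }

  # action on rooted ids; edge 6/7 follows its cherry through the relabeling
  rooted_action <- matrix(0L, 120L, 105L)
  for (s in 1:120) {
    sig <- perms[s, ]
    for (t in 1:15) {
      t2 <- topo_action[s, t]
      for (e in 1:7) {
        if (e <= 5L) {
          e2 <- sig[e]
        } else {
          p <- if (e == 6L) qt_pairs[t, 1:2] else qt_pairs[t, 3:4]
          pm <- .mask(sig[p])
          e2 <- if (pm == .mask(qt_pairs[t2, 1:2])) 6L else 7L
        }
        rooted_action[s, (t - 1L) * 7L + e] <- (t2 - 1L) * 7L + e2
      }
    }
  }

  # shape and nontrivial clade masks of each rooted quintet
  rq_shape <- character(105L)
  rq_clades <- vector("list", 105L)
  for (t in 1:15) {
    p1 <- qt_pairs[t, 1:2]; p2 <- qt_pairs[t, 3:4]
    lv <- lone[t]
    for (e in 1:7) {
      id <- (t - 1L) * 7L + e
      if (e <= 5L && e == lv) {
        rq_shape[id] <- "pseudo-caterpillar"
        rq_clades[[id]] <- c(.mask(p1), .mask(p2), .mask(c(p1, p2)))
      } else if (e <= 5L) {
        inP1 <- e %in% p1
        p <- if (inP1) p1 else p2
        q <- if (inP1) p2 else p1
        y <- setdiff(p, e)
        rq_shape[id] <- "caterpillar"
        rq_clades[[id]] <- c(.mask(q), .mask(c(q, lv)), .mask(c(q, lv, y)))
      } else {
        p <- if (e == 6L) p1 else p2
        q <- if (e == 6L) p2 else p1
        rq_shape[id] <- "balanced"
        rq_clades[[id]] <- c(.mask(p), .mask(q), .mask(c(q, lv)))
      }
      rq_clades[[id]] <- sort(rq_clades[[id]])
    }
  }
  rq_key <- vapply(rq_clades, paste, "", collapse = ".")
  names(rq_key) <- NULL
  rq_id_by_key <- setNames(seq_len(105L), rq_key)

  # reference rooted trees of the three shapes (see adr_tables.R)
  ref_ids <- c(caterpillar = 19L, balanced = 21L, `pseudo-caterpillar` = 17L)

  # one permutation carrying the shape's reference tree onto each rooted id
  rq_sigma <- integer(105L)
  for (s in 1:120) {
    for (shp in names(ref_ids)) {
      r <- rooted_action[s, ref_ids[[shp]]]
      if (rq_sigma[r] == 0L) rq_sigma[r] <- s
    }
  }

  qt <- list(pairs = qt_pairs, lone = lone, pair_lookup = pair_lookup,
             perms = perms, perm_key = perm_key,
             topo_action = topo_action, rooted_action = rooted_action,
             rq_shape = rq_shape, rq_clades = rq_clades,
             rq_id_by_key = rq_id_by_key, ref_ids = ref_ids,
             rq_sigma = rq_sigma)
  .qr_cache$qt <- qt
  qt
}

#' Newick string of a canonical unrooted quintet topology
#'
#' @param index Integer in 1..15, the canonical topology index (lexicographic
#'   rank of the sorted cherry pairs over the ordered leaf positions).
#' @param labels Character vector of 5 leaf labels for positions 1..5.
#' @return A newick string with a basal trichotomy (unrooted).
#' @export
quintet_newick <- function(index, labels = letters[1:5]) {
  stopifnot(length(index) == 1L, index %in% 1:15, length(labels) == 5L)
  qt <- .qt()
  p <- qt$pairs[index, ]
  sprintf("((%s,%s),%s,(%s,%s));", labels[p[1]], labels[p[2]],
          labels[qt$lone[index]], labels[p[3]], labels[p[4]])
}

#' Newick string of a canonical rooted quintet topology
#'
#' @param id Integer in 1..105, the rooted quintet id
#'   (`(topology - 1) * 7 + edge`).
#' @param labels Character vector of 5 leaf labels for positions 1..5.
#' @return A newick string with a degree-2 root.
#' @export
rooted_quintet_newick <- function(id, labels = letters[1:5]) {
  stopifnot(length(id) == 1L, id %in% 1:105, length(labels) == 5L)
  qt <- .qt()
  t <- (id - 1L) %/% 7L + 1L
  e <- (id - 1L) %% 7L + 1L
  p1 <- qt$pairs[t, 1:2]; p2 <- qt$pairs[t, 3:4]; lv <- qt$lone[t]
  L <- function(i) labels[i]
  if (e <= 5L && e == lv) {
    sprintf("(((%s,%s),(%s,%s)),%s);", L(p1[1]), L(p1[2]), L(p2[1]), L(p2[2]), L(lv))
  } else if (e <= 5L) {
    inP1 <- e %in% p1
    p <- if (inP1) p1 else p2
    q <- if (inP1) p2 else p1
    y <- setdiff(p, e)
    sprintf("((((%s,%s),%s),%s),%s);", L(q[1]), L(q[2]), L(lv), L(y), L(e))
  } else {
    p <- if (e == 6L) p1 else p2
    q <- if (e == 6L) p2 else p1
    sprintf("((%s,%s),((%s,%s),%s));", L(p[1]), L(p[2]), L(q[1]), L(q[2]), L(lv))
  }
}

#' Enumerate the 15 unrooted quintet topologies
#'
#' Returns the canonical catalogue of unrooted binary topologies on five
#' leaves, in the package's canonical order (lexicographic on the sorted
#' cherry pairs).
#'
#' @param labels Character vector of 5 leaf labels for positions 1..5.
#' @return A `multiPhylo` of 15 unrooted trees; element `i` has canonical
#'   topology index `i`.
#' @export
quintet_topologies <- function(labels = letters[1:5]) {
  trees <- lapply(1:15, function(i) ape::read.tree(text = quintet_newick(i, labels)))
  class(trees) <- "multiPhylo"
  trees
}

#' Enumerate the 105 rooted quintet topologies
#'
#' All rootings (7 edges) of all 15 unrooted quintet topologies; the id of
#' element `r` is `r` itself.
#'
#' @param labels Character vector of 5 leaf labels for positions 1..5.
#' @return A `multiPhylo` of 105 rooted trees, with a `"shape"` attribute
#'   giving each tree's shape category.
#' @export
rooted_quintets <- function(labels = letters[1:5]) {
  trees <- lapply(1:105, function(i) ape::read.tree(text = rooted_quintet_newick(i, labels)))
  class(trees) <- "multiPhylo"
  attr(trees, "shape") <- .qt()$rq_shape
  trees
}

#' Shape category of a rooted five-leaf tree
#'
#' Classifies a rooted binary quintet as `"caterpillar"` (root split 1|4 with
#' nested 1|3, 1|2 splits), `"balanced"` (root split 2|3) or
#' `"pseudo-caterpillar"` (root split 1|4 over two cherries).
#'
#' @param tree A rooted binary `phylo` with exactly 5 tips, or a rooted
#'   quintet id in 1..105.
#' @return One of `"caterpillar"`, `"balanced"`, `"pseudo-caterpillar"`.
#' @export
classify_shape <- function(tree) {
  if (is.numeric(tree)) {
    stopifnot(length(tree) == 1L, tree %in% 1:105)
    return(.qt()$rq_shape[tree])
  }
  .qt()$rq_shape[rooted_quintet_id(tree)]
}

# ordered positions 1..5 of a quintet's taxa; default lexicographic
.quintet_positions <- function(tree, taxa = NULL) {
  if (is.null(taxa)) taxa <- sort(tree$tip.label)
  if (length(taxa) != 5L || anyDuplicated(taxa))
    stop("`taxa` must give 5 distinct labels")
  if (!setequal(taxa, tree$tip.label))
    stop("tree labels do not match `taxa`: ",
         paste(setdiff(taxa, tree$tip.label), collapse = ", "))
  match(tree$tip.label, taxa)                  # tip i of tree -> position
}

# tip sets (as position masks) below each internal edge of a phylo
.internal_edge_masks <- function(tree, pos) {
  ntip <- length(tree$tip.label)
  internal <- tree$edge[, 2] > ntip
  nodes <- tree$edge[internal, 2]
  vapply(nodes, function(nd) {
    tips <- unlist(phangorn::Descendants(tree, nd, "tips"))
    .mask(pos[tips])
  }, integer(1))
}

#' Canonical index of an unrooted quintet topology
#'
#' @param tree An unrooted binary `phylo` with exactly 5 tips.
#' @param taxa Optional character vector of the 5 labels in the order that
#'   maps them onto positions 1..5; defaults to the sorted labels.
#' @return Integer in 1..15.
#' @export
topology_index <- function(tree, taxa = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) != 5L) stop("not a quintet: ", length(tree$tip.label), " tips")
  tree <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  if (tree$Nnode != 3L) stop("unresolved quintet (non-binary tree)")
  pos <- .quintet_positions(tree, taxa)
  masks <- .internal_edge_masks(tree, pos)
  # each internal edge gives one split; take the 2-leaf side as the cherry
  cherries <- vapply(masks, function(m) {
    if (.POPCNT5[m + 1L] == 2L) m else bitwAnd(bitwNot(m), 31L)
  }, integer(1))
  cherries <- sort(unique(cherries))
  if (length(cherries) != 2L) stop("unresolved quintet (non-binary tree)")
  t <- .qt()$pair_lookup[cherries[1] * 32L + cherries[2] + 1L]
  if (t == 0L) stop("internal error: invalid cherry pair")
  t
}

# rooted quintet id from the three nontrivial clade masks
.rooted_id_from_masks <- function(masks) {
  masks <- sort(unique(masks))
  if (length(masks) != 3L) stop("not a binary rooted quintet clade set")
  id <- .qt()$rq_id_by_key[paste(masks, collapse = ".")]
  if (is.na(id)) stop("not a binary rooted quintet clade set")
  unname(id)
}

#' Canonical id of a rooted quintet topology
#'
#' @inheritParams topology_index
#' @param tree A rooted binary `phylo` with exactly 5 tips.
#' @return Integer in 1..105; `(id - 1) %/% 7 + 1` is the unrooted topology
#'   index and `(id - 1) %% 7 + 1` the root edge.
#' @export
rooted_quintet_id <- function(tree, taxa = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) != 5L) stop("not a quintet: ", length(tree$tip.label), " tips")
  if (!ape::is.rooted(tree) || tree$Nnode != 4L)
    stop("tree is not a rooted binary quintet")
  pos <- .quintet_positions(tree, taxa)
  ntip <- 5L
  nodes <- setdiff(unique(tree$edge[, 1]), ntip + 1L)  # internal, minus root
  masks <- vapply(nodes, function(nd) {
    .mask(pos[unlist(phangorn::Descendants(tree, nd, "tips"))])
  }, integer(1))
  .rooted_id_from_masks(masks)
}

# row index of a permutation of 1:5 in the canonical table
.perm_index <- function(perm) {
  stopifnot(length(perm) == 5L, setequal(perm, 1:5))
  match(paste(perm, collapse = ""), .qt()$perm_key)
}

#' Apply a leaf relabeling to a quintet topology index
#'
#' The permutation `perm` sends the leaf at position `i` to position
#' `perm[i]`; the return value is the index of the relabeled topology.
#'
#' @param index Topology index: 1..15 if `rooted = FALSE`, 1..105 otherwise.
#' @param perm Integer vector, a permutation of 1:5.
#' @param rooted Whether `index` is a rooted quintet id.
#' @return The relabeled index, same kind as the input.
#' @export
apply_leaf_permutation <- function(index, perm, rooted = FALSE) {
  qt <- .qt()
  s <- .perm_index(perm)
  if (rooted) {
    stopifnot(all(index %in% 1:105))
    qt$rooted_action[s, index]
  } else {
    stopifnot(all(index %in% 1:15))
    qt$topo_action[s, index]
  }
}
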