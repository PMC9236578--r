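## ADR equivalence classes and inequality partial orders for the 105 rooted
## quintet topologies.
##
## Under the MSC, a rooted five-taxon species tree constrains the probability
## vector (u1..u15) of unrooted gene-tree topologies: probabilities within an
## equivalence class are equal for every choice of branch lengths (the
## invariants), and certain classes strictly dominate others (the
## inequalities).  Both depend only on the shape of the rooted tree.  The
## three base structures below are stated for the reference trees
##   caterpillar          ((((a,b),c),d),e)
##   balanced             (((a,b),c),(d,e))
##   pseudo-caterpillar   (((a,b),(d,e)),c)
## and every other rooted quintet's structure is their image under the leaf
## relabeling that carries the reference tree onto it.
##
## The u-index convention: u1 is the unrooted topology of the species tree
## itself; the full bijection between the ADR indices u1..u15 and this
## package's canonical topology indices is the constant .U2T below.  It is
## pinned (up to within-class swaps that provably change nothing) by the
## requirement that the three printed class partitions are unions of orbits
## of each reference tree's parameter-free automorphisms; a Monte-Carlo test
## re-verifies it against simulated distributions.  The inequality pair sets
## reproduce the published term-count checksums: 18/23/31 invariant terms,
## 28/44/54 inequality terms, weighted counts 19/20/19.

# ADR index -> canonical topology index (positions a..e = 1..5):
# u1={ab,de} u2={ab,ce} u3={ab,cd} u4={ac,de} u5={ac,be} u6={ac,bd}
# u7={ad,ce} u8={ad,be} u9={ad,bc} u10={ae,cd} u11={ae,bd} u12={ae,bc}
# u13={bc,de} u14={bd,ce} u15={be,cd}
.U2T <- c(3L, 2L, 1L, 6L, 5L, 4L, 9L, 8L, 7L, 12L, 11L, 10L, 13L, 14L, 15L)

# base equivalence classes (ADR u-indices) and class-level order pairs
.ADR_BASE <- list(
  caterpillar = list(
    classes = list(1L, 2L, 3L, c(4L, 13L), c(6L, 9L), c(5L, 12L),
                   c(7L, 8L, 10L, 11L, 14L, 15L)),
    order = rbind(c(1L, 2L), c(3L, 2L), c(3L, 4L), c(3L, 5L),
                  c(2L, 6L), c(4L, 6L), c(5L, 6L), c(6L, 7L))
  ),
  balanced = list(
    classes = list(1L, c(2L, 3L), c(4L, 13L), c(5L, 6L, 9L, 12L),
                   c(7L, 8L, 10L, 11L, 14L, 15L)),
    order = rbind(c(1L, 2L), c(1L, 3L), c(2L, 4L), c(3L, 4L), c(4L, 5L))
  ),
  `pseudo-caterpillar` = list(
    classes = list(1L, c(2L, 3L), c(4L, 13L), c(8L, 11L),
                   c(5L, 6L, 7L, 9L, 10L, 12L, 14L, 15L)),
    order = rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L),
                  c(2L, 5L), c(3L, 5L), c(4L, 5L))
  )
)

# canonicalize a structure: classes sorted internally and by smallest member,
# order pairs remapped and sorted rowwise
.canonical_structure <- function(classes, pairs) {
  classes <- lapply(classes, sort)
  o <- order(vapply(classes, min, integer(1)))
  classes <- classes[o]
  remap <- integer(length(o)); remap[o] <- seq_along(o)
  pairs <- cbind(remap[pairs[, 1]], remap[pairs[, 2]])
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  list(classes = classes, order = pairs)
}

.new_adr_structure <- function(id, shape, classes, order) {
  cs <- .canonical_structure(classes, order)
  structure(list(id = id, shape = shape,
                 classes = cs$classes, order = cs$order),
            class = "adr_structure")
}

# all 105 structures, in canonical topology-index space, cached
.adr_all <- function() {
  if (!is.null(.qr_cache$adr_all)) return(.qr_cache$adr_all)
  qt <- .qt()
  out <- vector("list", 105L)
  for (r in 1:105) {
    shape <- qt$rq_shape[r]
    base <- .ADR_BASE[[shape]]
    s <- qt$rq_sigma[r]
    classes <- lapply(base$classes, function(cl) qt$topo_action[s, .U2T[cl]])
    out[[r]] <- .new_adr_structure(r, shape, classes, base$order)
  }
  .qr_cache$adr_all <- out
  out
}

#' ADR invariant/inequality structure of a rooted quintet
#'
#' Returns the equivalence classes (sets of canonical unrooted-topology
#' indices whose gene-tree probabilities are equal under the MSC for every
#' branch-length choice) and the inequality partial order (ordered class
#' pairs `(c, c')` meaning every probability in `c` exceeds every probability
#' in `c'`) for one rooted quintet topology.
#'
#' @param x A rooted quintet id in 1..105, a shape name (`"caterpillar"`,
#'   `"balanced"`, `"pseudo-caterpillar"`; returns the structure of that
#'   shape's reference tree), or a rooted binary 5-leaf `phylo`.
#' @param taxa Passed to [rooted_quintet_id()] when `x` is a tree.
#' @return An object of class `adr_structure`: a list with elements `id`,
#'   `shape`, `classes` (list of integer vectors partitioning 1..15) and
#'   `order` (two-column matrix of class indices, greater class first).
#' @examples
#' adr_structure("caterpillar")$classes
#' @export
adr_structure <- function(x, taxa = NULL) {
  if (is.character(x)) {
    x <- match.arg(x, names(.ADR_BASE))
    return(.adr_all()[[.qt()$ref_ids[[x]]]])
  }
  if (inherits(x, "phylo")) x <- rooted_quintet_id(x, taxa)
  stopifnot(length(x) == 1L, x %in% 1:105)
  .adr_all()[[x]]
}

#' All 105 ADR structures
#'
#' @return List of 105 `adr_structure` objects indexed by rooted quintet id.
#' @export
adr_structures <- function() .adr_all()

#' Penalty-term counts of an ADR structure
#'
#' The invariant penalty of the quintet cost contributes one term per
#' unordered pair within an equivalence class, `sum_c choose(|c|, 2)` terms
#' in total; the inequality penalty contributes `|c| * |c'|` terms per
#' ordered class pair.  The weighted counts apply the cost's normalization
#' factors: `1/|c|` per invariant class (counting the `|c|(|c|-1)` ordered
#' pairs, i.e. `sum_c (|c| - 1)`) and `1/|c'|` per inequality pair
#' (`sum_{c>c'} |c|`).
#'
#' @param structure An `adr_structure`, or anything accepted by
#'   [adr_structure()].
#' @return List with `invariant_terms`, `inequality_terms`, `total_terms`,
#'   `weighted_invariants`, `weighted_inequalities`, `weighted_total`.
#' @examples
#' count_penalty_terms(adr_structure("caterpillar"))$invariant_terms  # 18
#' @export
count_penalty_terms <- function(structure) {
  if (!inherits(structure, "adr_structure")) structure <- adr_structure(structure)
  sz <- lengths(structure$classes)
  inv <- as.integer(sum(choose(sz, 2)))
  hi <- sz[structure$order[, 1]]; lo <- sz[structure$order[, 2]]
  ineq <- as.integer(sum(hi * lo))
  winv <- as.integer(sum(sz - 1L))
  wineq <- as.integer(sum(hi))
  list(invariant_terms = inv, inequality_terms = ineq,
       total_terms = inv + ineq,
       weighted_invariants = winv, weighted_inequalities = wineq,
       weighted_total = winv + wineq)
}

#' @export
print.adr_structure <- function(x, ...) {
  t2u <- integer(15L); t2u[.U2T] <- 1:15
  cat(sprintf("ADR structure for rooted quintet %d (%s)\n", x$id, x$shape))
  fmt <- vapply(x$classes, function(cl)
    paste0("{", paste0("u", sort(t2u[cl]), collapse = ","), "}"), "")
  cat("  classes:", paste(fmt, collapse = " "), "\n")
  cat("  order:  ",
      paste(sprintf("%s > %s", fmt[x$order[, 1]], fmt[x$order[, 2]]),
            collapse = "; "), "\n")
  invisible(x)
}

#' Map canonical topology indices to ADR u-indices and back
#'
#' The package enumerates the 15 unrooted quintet topologies
#' lexicographically by their cherry pairs; the ADR literature numbers them
#' u1..u15 with u1 the species tree's own unrooted topology for the
#' reference trees.  These helpers convert between the two conventions.
#'
#' @param i Canonical topology indices (1..15).
#' @param u ADR u-indices (1..15).
#' @return Integer vector of the corresponding indices.
#' @export
as_adr_index <- function(i) {
  stopifnot(all(i %in% 1:15))
  t2u <- integer(15L); t2u[.U2T] <- 1:15
  t2u[i]
}

#' @rdname as_adr_index
#' @export
from_adr_index <- function(u) {
  stopifnot(all(u %in% 1:15))
  .U2T[u]
}

#' Tabular export of the 105 ADR structures
#'
#' One row per rooted quintet id, with the newick of the rooted topology,
#' its shape, the class partition and the order pairs in a plain-text
#' encoding (classes as `|`-separated blocks of ADR u-indices; order pairs
#' as `i>j` class-index pairs).
#'
#' @return A data.frame with columns `id`, `newick`, `shape`, `classes`,
#'   `order`.
#' @export
adr_table <- function() {
  t2u <- integer(15L); t2u[.U2T] <- 1:15
  rows <- lapply(.adr_all(), function(s) {
    data.frame(
      id = s$id,
      newick = rooted_quintet_newick(s$id),
      shape = s$shape,
      classes = paste(vapply(s$classes, function(cl)
        paste(sort(t2u[cl]), collapse = ","), ""), collapse = "|"),
      order = paste(sprintf("%d>%d", s$order[, 1], s$order[, 2]), collapse = " "),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
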