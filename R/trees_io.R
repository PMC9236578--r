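## Newick I/O, validation, taxon restriction, canonical edge enumeration and
## rerooting.  Thin, validated layer over ape.

#' Read newick trees
#'
#' Reads one or more newick trees from a file (one tree per line for
#' multi-tree files) or from a literal newick string.  The rooted flag of
#' each tree follows its root degree: a degree-2 root means rooted, a
#' degree-3 (or higher) root means unrooted.
#'
#' @param x Path to a newick file, or a character scalar containing newick
#'   text (anything with a `;`).
#' @return A `multiPhylo` list of trees (length 1 for a single tree).
#' @export
read_trees <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  from_file <- !grepl(";", x, fixed = TRUE)
  if (from_file && !file.exists(x)) stop("file not found: ", x)
  trees <- tryCatch(
    if (from_file) ape::read.tree(x) else ape::read.tree(text = x),
    error = function(e) NULL)
  if (is.null(trees) && from_file) {
    # locate the offending line for the error message
    lines <- readLines(x, warn = FALSE)
    for (i in seq_along(lines)) {
      if (!nzchar(trimws(lines[i]))) next
      ok <- tryCatch({ape::read.tree(text = lines[i]); TRUE},
                     error = function(e) FALSE, warning = function(w) FALSE)
      if (!ok) stop("malformed newick on line ", i, " of ", x)
    }
  }
  if (is.null(trees)) stop("malformed newick input")
  if (inherits(trees, "phylo")) {
    trees <- list(trees)
    class(trees) <- "multiPhylo"
  }
  for (i in seq_along(trees)) {
    dup <- trees[[i]]$tip.label[duplicated(trees[[i]]$tip.label)]
    if (length(dup))
      stop("duplicate leaf labels in tree ", i, ": ",
           paste(unique(dup), collapse = ", "))
  }
  trees
}

#' Write newick trees, one per line
#'
#' @param trees A `phylo` or `multiPhylo`.
#' @param file Output path.
#' @export
write_trees <- function(trees, file) {
  if (inherits(trees, "phylo")) { trees <- list(trees); class(trees) <- "multiPhylo" }
  ape::write.tree(trees, file = file)
  invisible(file)
}

#' Restrict a tree to a taxon subset
#'
#' Induced subtree on `taxa`: pruned leaves are removed, degree-2 nodes are
#' suppressed and their branch lengths summed.  A rooted input stays rooted
#' (the root moves to the MRCA of `taxa`); an unrooted input stays unrooted.
#'
#' @param tree A `phylo`.
#' @param taxa Character vector of leaf labels, all present in `tree`,
#'   at least 3 of them.
#' @return The induced `phylo`.
#' @export
restrict_tree <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"))
  if (length(taxa) < 3L) stop("need at least 3 taxa to restrict to")
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  was_rooted <- ape::is.rooted(tree)
  out <- ape::keep.tip(tree, taxa)
  if (!was_rooted && ape::is.rooted(out)) out <- ape::unroot(out)
  out
}

#' Canonical edge table of a tree
#'
#' Enumerates the edges of a tree with stable, topology-determined
#' identifiers, so that candidate rootings are reproducible across runs.
#' Each edge is identified by the leaf set on its far side (the side not
#' containing the lexicographically smallest label); edges are ordered by
#' the size of that set, then lexicographically by its labels.
#'
#' @param tree A `phylo`.
#' @return A data.frame with columns `edge` (canonical id 1..E), `row`
#'   (row in `tree$edge`), `split` (far-side labels, `|`-separated) and
#'   `size` (far-side leaf count).
#' @export
tree_edges <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  anchor <- min(tree$tip.label)
  sets <- lapply(seq_len(nrow(tree$edge)), function(i) {
    child <- tree$edge[i, 2]
    tips <- if (child <= ntip) tree$tip.label[child]
            else tree$tip.label[unlist(phangorn::Descendants(tree, child, "tips"))]
    if (anchor %in% tips) setdiff(tree$tip.label, tips) else tips
  })
  split <- vapply(sets, function(s) paste(sort(s), collapse = "|"), "")
  size <- lengths(sets)
  o <- order(size, split)
  data.frame(edge = seq_along(o), row = o, split = split[o], size = size[o],
             stringsAsFactors = FALSE)
}

#' Root an unrooted tree on one of its edges
#'
#' Produces the rooted binary tree whose degree-2 root subdivides the chosen
#' edge; unrooting the result recovers the input topology.
#'
#' @param tree An unrooted binary `phylo`.
#' @param edge Canonical edge id, as given by [tree_edges()].
#' @return A rooted `phylo`.
#' @export
reroot_on_edge <- function(tree, edge) {
  stopifnot(inherits(tree, "phylo"))
  ed <- tree_edges(tree)
  if (!(edge %in% ed$edge)) stop("invalid edge id: ", edge)
  far <- strsplit(ed$split[ed$edge == edge], "|", fixed = TRUE)[[1]]
  og <- if (length(far) <= length(tree$tip.label) / 2) far
        else setdiff(tree$tip.label, far)
  out <- ape::root(tree, outgroup = og, resolve.root = TRUE)
  stopifnot(ape::is.rooted(out))
  out
}
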