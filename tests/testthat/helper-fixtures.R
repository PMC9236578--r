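# Shared fixtures and independent oracles for the test suite.

REF_NEWICK <- c(
  caterpillar          = "((((a,b),c),d),e);",
  balanced             = "(((a,b),c),(d,e));",
  `pseudo-caterpillar` = "(((a,b),(d,e)),c);"
)

ref_tree <- function(shape) ape::read.tree(text = REF_NEWICK[[shape]])

# A distribution exactly compatible with a structure: equal within classes,
# strictly decreasing along the order DAG (longest-path levels).
compatible_distribution <- function(st, gap = 1) {
  nc <- length(st$classes)
  level <- rep(0L, nc)
  repeat {
    changed <- FALSE
    for (p in seq_len(nrow(st$order))) {
      hi <- st$order[p, 1]; lo <- st$order[p, 2]
      if (level[lo] < level[hi] + 1L) { level[lo] <- level[hi] + 1L; changed <- TRUE }
    }
    if (!changed) break
  }
  vals <- max(level) + 1 - level          # higher class -> larger value
  u <- numeric(15)
  for (i in seq_len(nc)) u[st$classes[[i]]] <- vals[i] * gap
  u / sum(u)
}

# Literal term-by-term expansion of the cost from a structure object;
# independent of the package's flattened-index implementation.
oracle_cost <- function(u, st, variant = 4L) {
  inv <- 0
  for (cl in st$classes) {
    if (length(cl) < 2) next
    part <- 0
    # ordered pairs: every (a, b), a != b, contributes
    for (a in seq_along(cl)) for (b in seq_along(cl)) {
      if (a != b) part <- part + abs(u[cl[a]] - u[cl[b]])
    }
    inv <- inv + if (variant == 2L) part else part / length(cl)
  }
  if (variant == 1L) return(inv)
  ineq <- 0
  for (p in seq_len(nrow(st$order))) {
    hi <- st$classes[[st$order[p, 1]]]
    lo <- st$classes[[st$order[p, 2]]]
    part <- 0
    for (a in hi) for (b in lo) part <- part + max(0, u[b] - u[a])
    ineq <- ineq + if (variant == 2L) part else part / length(lo)
  }
  inv + ineq
}

# random normalized quintet distribution
random_u15 <- function() {
  u <- runif(15)
  u / sum(u)
}

# splits (as sorted-label signatures, side not containing the smallest
# label) of an unrooted tree -- independent bipartition oracle for RF
split_signatures <- function(tree) {
  ed <- tree_edges(tree)
  sort(ed$split[ed$size >= 2 & ed$size <= length(tree$tip.label) - 2])
}

# standalone nontrivial-clade signatures (independent of the package's
# internal helper)
.clade_sig_for_test <- function(tree) {
  ntip <- length(tree$tip.label)
  nodes <- setdiff(unique(tree$edge[, 1]), ntip + 1L)
  vapply(nodes, function(nd) {
    tips <- tree$tip.label[unlist(phangorn::Descendants(tree, nd, "tips"))]
    paste(sort(tips), collapse = "|")
  }, "")
}

# all 120 permutations of 1:5, independently generated
combinat_perms5 <- function() {
  rec <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in rec(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  rec(1:5)
}
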