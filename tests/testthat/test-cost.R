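test_that("empirical quintet distributions tally restricted gene trees", {
  cat5 <- ref_tree("caterpillar")
  # point mass: identical gene trees
  gts <- rep(list(ape::unroot(cat5)), 12)
  class(gts) <- "multiPhylo"
  fr <- quintet_frequencies(gts, letters[1:5])
  expect_equal(sum(fr), 1)
  expect_equal(sum(as.numeric(fr) > 0), 1L)
  expect_equal(which(as.numeric(fr) > 0), topology_index(ape::unroot(cat5)))
  expect_equal(attr(fr, "support"), 12L)

  # one gene tree of each topology: uniform 1/15
  fr2 <- quintet_frequencies(quintet_topologies(), letters[1:5])
  expect_equal(as.numeric(fr2), rep(1 / 15, 15))

  # gene trees lacking a taxon are excluded from numerator and denominator
  extra <- ape::read.tree(text = "((a,b),(c,d),f);")
  gts3 <- c(unclass(gts), list(extra))
  fr3 <- quintet_frequencies(gts3, letters[1:5])
  expect_equal(attr(fr3, "support"), 12L)
  expect_equal(attr(fr3, "n_missing"), 1L)

  # unresolved restrictions are dropped and counted
  poly <- ape::read.tree(text = "((a,b),c,d,e);")
  fr4 <- quintet_frequencies(c(unclass(gts), list(poly)), letters[1:5])
  expect_equal(attr(fr4, "support"), 12L)
  expect_equal(attr(fr4, "n_unresolved"), 1L)

  expect_error(quintet_frequencies(list(extra), letters[1:5]), "empty quintet support")
})

test_that("restriction-based and distance-based tallies agree on larger gene trees", {
  set.seed(21)
  for (rep in 1:10) {
    gt <- ape::unroot(ape::rtree(9))
    taxa <- sort(sample(gt$tip.label, 5))
    via_restrict <- topology_index(restrict_tree(gt, taxa))
    fr <- quintet_frequencies(list(gt), taxa)
    expect_equal(which(as.numeric(fr) > 0), via_restrict)
  }
})

test_that("cost is zero exactly on compatible and uniform distributions", {
  uni <- rep(1 / 15, 15)
  for (v in c(1L, 2L, 4L)) {
    expect_equal(quintet_cost(uni, 1:105, variant = v), rep(0, 105))
  }
  for (id in seq(1, 105, by = 7)) {
    st <- adr_structure(id)
    u <- compatible_distribution(st)
    expect_equal(quintet_cost(u, id), 0)
  }
})

test_that("cost matches a literal term-by-term expansion (oracle)", {
  set.seed(22)
  # point masses against the reference caterpillar
  st <- adr_structure("caterpillar")
  for (i in 1:15) {
    u <- numeric(15); u[i] <- 1
    expect_equal(quintet_cost(u, st$id), oracle_cost(u, st))
  }
  # random distributions across variants and topologies
  for (rep in 1:10) {
    u <- random_u15()
    ids <- sample(105L, 8)
    for (v in c(1L, 2L, 4L)) {
      expect_equal(quintet_cost(u, ids, variant = v),
                   vapply(ids, function(id) oracle_cost(u, adr_structure(id), v),
                          numeric(1)))
    }
  }
})

test_that("variant 1 ignores inequality violations; variant 2 drops weights", {
  st <- adr_structure("caterpillar")
  # equal within classes but with the order maximally reversed
  lev <- compatible_distribution(st)
  vals <- sort(unique(lev), decreasing = TRUE)
  u <- numeric(15)
  for (cl in st$classes) u[cl] <- max(lev) + min(lev) - lev[cl[1]]
  u <- u / sum(u)
  expect_equal(quintet_cost(u, st$id, variant = 1L), 0)
  expect_gt(quintet_cost(u, st$id, variant = 4L), 0)
  expect_gt(quintet_cost(u, st$id, variant = 2L),
            quintet_cost(u, st$id, variant = 4L))  # weights only shrink terms
  expect_error(quintet_cost(u, st$id, variant = 3L), "not available")
  expect_error(quintet_cost(rep(0.1, 15), st$id), "normalized")
})

test_that("cost is permutation-equivariant, nonnegative and bounded", {
  set.seed(23)
  for (rep in 1:15) {
    u <- random_u15()
    r <- sample(105L, 1)
    perm <- sample(5L)
    u2 <- numeric(15)
    u2[apply_leaf_permutation(1:15, perm)] <- u
    r2 <- apply_leaf_permutation(r, perm, rooted = TRUE)
    for (v in c(1L, 2L, 4L))
      expect_equal(quintet_cost(u2, r2, variant = v),
                   quintet_cost(u, r, variant = v))
    costs <- quintet_cost(u, 1:105)
    expect_true(all(costs >= 0))
    expect_true(all(costs <= 30))
  }
})
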