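test_that("uniform distributions give seven zero scores and a flagged tie", {
  t5 <- read_trees("((a,b),c,(d,e));")[[1]]
  fr <- rep(1 / 15, 15)
  res <- root_quintet(t5, freq = fr)
  expect_equal(res$candidates$score, rep(0, 7))
  expect_true(res$tie)
  expect_equal(res$candidates$edge[which.min(res$candidates$score)], 1L)
})

test_that("point-mass distributions reproduce the brute-force minimum", {
  set.seed(31)
  for (rep in 1:5) {
    t0 <- sample(15L, 1)
    t5 <- quintet_topologies()[[t0]]
    u <- numeric(15); u[t0] <- 1
    res <- root_quintet(t5, freq = u)
    brute <- quintet_cost(u, res$candidates$rooted_id)
    expect_equal(res$candidates$score, brute)
    expect_equal(min(res$candidates$score), min(quintet_cost(u, (t0 - 1L) * 7L + 1:7)))
  }
})

test_that("rooting recovers the simulating quintet under the MSC", {
  for (shape in names(REF_NEWICK)) {
    sp <- quintet_model_tree(shape, internal = 0.5)
    idx <- sim_quintet_indices(sp, 2e4, seed = 101L)
    fr <- tabulate(idx, 15) / length(idx)
    res <- root_quintet(ape::unroot(sp), freq = fr)
    expect_equal(clade_distance(res$rooted, sp)$normalized, 0)
    expect_false(res$tie)
  }
})

test_that("at n = 5 the general scorer reduces exactly to the quintet scorer", {
  sp <- quintet_model_tree("balanced", internal = 0.5)
  gts <- sim_gene_trees(sp, 300, seed = 32L)
  r1 <- root_quintet(ape::unroot(sp), gts)
  for (mode in c("all", "linear")) {
    r2 <- root_species_tree(ape::unroot(sp), gts, mode = mode)
    expect_equal(r2$n_subsets, 1L)
    expect_equal(r2$candidates$score, r1$candidates$score)
    expect_equal(clade_distance(r2$rooted, r1$rooted)$normalized, 0)
  }
})

test_that("cached subset scoring equals naive per-candidate recomputation", {
  set.seed(33)
  sp <- random_model_tree(6, internal_range = c(0.4, 0.8))
  gts <- sim_gene_trees(sp, 40, seed = 34L)
  t6 <- ape::unroot(sp)
  res <- root_species_tree(t6, gts, mode = "all")
  # naive oracle: restrict every candidate rooting to every subset
  ed <- tree_edges(t6)
  taxa <- sort(t6$tip.label)
  subsets <- combn(taxa, 5L)
  naive <- vapply(ed$edge, function(e) {
    rt <- reroot_on_edge(t6, e)
    total <- 0
    for (j in seq_len(ncol(subsets))) {
      q <- subsets[, j]
      fr <- quintet_frequencies(gts, q)
      rq <- restrict_tree(rt, q)
      total <- total + quintet_cost(fr, rooted_quintet_id(rq))
    }
    total
  }, numeric(1))
  expect_equal(res$candidates$score, naive)
  # each subset induces at most 7 distinct rooted quintets across candidates
  for (j in seq_len(ncol(subsets))) {
    q <- subsets[, j]
    ids <- vapply(ed$edge, function(e)
      rooted_quintet_id(restrict_tree(reroot_on_edge(t6, e), q)), integer(1))
    expect_lte(length(unique(ids)), 7L)
  }
})

test_that("scores are invariant under gene-tree input order", {
  set.seed(35)
  sp <- random_model_tree(7, internal_range = c(0.4, 0.8))
  gts <- sim_gene_trees(sp, 60, seed = 36L)
  r1 <- root_species_tree(ape::unroot(sp), gts, mode = "all")
  r2 <- root_species_tree(ape::unroot(sp), gts[sample(60)], mode = "all")
  expect_equal(r1$candidates$score, r2$candidates$score)
})

test_that("linear mode uses O(n) subsets and recovers an 8-taxon root", {
  set.seed(37)
  sp <- random_model_tree(8, internal_range = c(0.5, 0.5))
  gts <- sim_gene_trees(sp, 5000, seed = 38L)
  t8 <- ape::unroot(sp)
  res_all <- root_species_tree(t8, gts, mode = "all")
  expect_equal(res_all$n_subsets, choose(8, 5))
  expect_equal(clade_distance(res_all$rooted, sp)$normalized, 0)
  res_lin <- root_species_tree(t8, gts, mode = "linear")
  expect_lte(res_lin$n_subsets, 8L - 3L)
  expect_equal(nrow(res_lin$candidates), 2L * 8L - 3L)
})

test_that("gene trees with missing taxa are used where they qualify", {
  set.seed(39)
  sp <- random_model_tree(6, internal_range = c(0.5, 0.5))
  gts <- sim_gene_trees(sp, 300, seed = 40L)
  # drop one taxon from half the gene trees
  for (i in seq(1, 300, by = 2))
    gts[[i]] <- ape::drop.tip(gts[[i]], sp$tip.label[1])
  res <- root_species_tree(ape::unroot(sp), gts, mode = "all")
  expect_equal(res$n_skipped, 0L)  # every subset still has some support
  expect_equal(clade_distance(res$rooted, sp)$normalized, 0)
  expect_error(root_species_tree(ape::unroot(sp),
                                 lapply(gts[1:2], function(g) ape::rtree(4)),
                                 mode = "all"),
               "no five-taxon subset")
})
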