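test_that("simulation is deterministic under a seed and streams agree", {
  sp <- quintet_model_tree("balanced", internal = 0.5)
  g1 <- sim_gene_trees(sp, 25, seed = 51L)
  g2 <- sim_gene_trees(sp, 25, seed = 51L)
  expect_equal(ape::write.tree(g1), ape::write.tree(g2))
  # the index fast path consumes the identical random stream
  idx <- sim_quintet_indices(sp, 25, seed = 51L)
  expect_equal(idx, vapply(g1, topology_index, integer(1)))
})

test_that("simulated gene trees are valid rooted binary phylo objects", {
  set.seed(52)
  sp <- random_model_tree(7, internal_range = c(0.3, 1))
  gts <- sim_gene_trees(sp, 20, seed = 53L, unrooted = FALSE)
  for (g in gts) {
    chk <- utils::capture.output(ape::checkValidPhylo(g))
    expect_false(any(grepl("FATAL|MODERATE", chk)))
    expect_true(ape::is.rooted(g))
    expect_true(ape::is.binary(g))
    expect_setequal(g$tip.label, sp$tip.label)
    expect_true(all(g$edge.length >= 0))
  }
  # ultrametric species tree (equal tip depths) => ultrametric gene trees
  spu <- quintet_model_tree("caterpillar", internal = 0.5, terminal = 2)
  spu$edge.length[spu$edge[, 2] <= 5] <-
    spu$edge.length[spu$edge[, 2] <= 5] +
    (max(ape::node.depth.edgelength(spu)[1:5]) -
       ape::node.depth.edgelength(spu)[1:5])
  gtu <- sim_gene_trees(spu, 10, seed = 54L, unrooted = FALSE)
  for (g in gtu) expect_true(ape::is.ultrametric(g, tol = 1e-8))
})

test_that("long interior branches give nearly complete concordance", {
  # P(no deep coalescence per 10-CU branch) = 1 - exp(-10); with three
  # interior branches, > 99% of gene trees match the species tree
  sp <- quintet_model_tree("caterpillar", internal = 10)
  idx <- sim_quintet_indices(sp, 4000, seed = 55L)
  match_rate <- mean(idx == topology_index(ape::unroot(sp)))
  expect_gte(match_rate, 0.99)
})

test_that("a near-star tree approaches the exchangeable uniform distribution", {
  # leaf exchangeability makes all 15 labeled topologies equiprobable
  sp <- quintet_model_tree("balanced", internal = 1e-4)
  k <- 3e4
  idx <- sim_quintet_indices(sp, k, seed = 56L)
  u <- tabulate(idx, 15) / k
  zcrit <- qnorm(1 - 1e-4 / 30)  # Bonferroni over 15 cells
  for (i in 1:15) {
    z <- abs(u[i] - 1 / 15) / sqrt((1 / 15) * (14 / 15) / k)
    expect_lt(z, zcrit)
  }
})

test_that("the most frequent topology matches the species tree at moderate ILS", {
  for (shape in names(REF_NEWICK)) {
    sp <- quintet_model_tree(shape, internal = 0.5)
    idx <- sim_quintet_indices(sp, 2e4, seed = 57L)
    expect_equal(which.max(tabulate(idx, 15)),
                 topology_index(ape::unroot(sp)))
  }
})

test_that("clock perturbation rescales lengths but never topologies", {
  sp <- quintet_model_tree("caterpillar", internal = 0.5)
  gts <- sim_gene_trees(sp, 50, seed = 58L)
  same <- perturb_clock(gts, 0, seed = 59L)
  expect_equal(ape::write.tree(same), ape::write.tree(gts))

  pert <- perturb_clock(gts, sigma = 0.6, seed = 60L)
  expect_equal(vapply(pert, topology_index, integer(1)),
               vapply(gts, topology_index, integer(1)))
  # quintet rooting consumes topologies only: identical result
  r1 <- root_quintet(ape::unroot(sp), gts)
  r2 <- root_quintet(ape::unroot(sp), pert)
  expect_equal(r1$candidates$score, r2$candidates$score)

  # lognormal moment check: mean factor ~ exp(sigma^2 / 2)
  big <- perturb_clock(rep(gts, 40), sigma = 0.5, seed = 61L)
  ratios <- unlist(lapply(seq_along(big), function(i)
    big[[i]]$edge.length / rep(gts, 40)[[i]]$edge.length))
  expect_equal(mean(ratios), exp(0.5^2 / 2), tolerance = 0.03)
})

test_that("NNI perturbation changes roughly the stated fraction of trees", {
  sp <- quintet_model_tree("caterpillar", internal = 2)
  gts <- sim_gene_trees(sp, 200, seed = 62L)
  pert <- perturb_nni(gts, prob = 0.5, seed = 63L)
  changed <- mean(vapply(seq_along(gts), function(i)
    topology_index(pert[[i]]) != topology_index(gts[[i]]), logical(1)))
  expect_gt(changed, 0.25)
  expect_lt(changed, 0.6)
  none <- perturb_nni(gts, prob = 0, seed = 64L)
  expect_equal(ape::write.tree(none), ape::write.tree(gts))
})

test_that("invalid model trees are rejected", {
  sp <- quintet_model_tree("caterpillar", internal = 0.5)
  expect_error(sim_gene_trees(ape::unroot(sp), 5), "rooted")
  sp$edge.length <- NULL
  expect_error(sim_gene_trees(sp, 5), "branch lengths")
  sp2 <- quintet_model_tree("caterpillar", internal = 0.5)
  sp2$edge.length[sp2$edge[, 2] > 5][1] <- 0
  expect_error(sim_gene_trees(sp2, 5), "positive")
})
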