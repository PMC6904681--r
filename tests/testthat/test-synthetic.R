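test_that("simulated chronograms are seeded, ultrametric and sized as asked", {
  cherry <- simulate_chronogram(2, 40, seed = 1)
  expect_length(cherry$tip.label, 2)
  expect_equal(max(node_ages(cherry)), 40)
  t1 <- simulate_chronogram(15, 120, seed = 2)
  expect_length(t1$tip.label, 15)
  expect_silent(node_ages(t1))
  expect_identical(write_newick(t1),
                   write_newick(simulate_chronogram(15, 120, seed = 2)))
  expect_false(identical(write_newick(t1),
                         write_newick(simulate_chronogram(15, 120, seed = 3))))
  expect_error(simulate_chronogram(1, 10), "n_tips")
  expect_error(simulate_chronogram(5, 0), "root_age")
})

test_that("rate categories follow the Markov switching scheme", {
  tr <- simulate_chronogram(30, 100, seed = 4)
  # switch_prob = 0: every non-root-child branch inherits its parent branch
  ra0 <- assign_rates(tr, 3, c(1e-4, 1e-3, 1e-2), 0, seed = 5)
  root <- 31
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]
    if (p == root) next
    pe <- which(tr$edge[, 2] == p)
    expect_identical(ra0$category[e], ra0$category[pe])
  }
  # k = 1: everything identical
  ra1 <- assign_rates(tr, 1, 7e-4, 0.5, seed = 6)
  expect_identical(unique(ra1$category), 1L)
  expect_identical(unique(ra1$rate), 7e-4)
  # switch_prob = 1 on a large tree: frequencies compatible with uniform
  big <- simulate_chronogram(400, 100, seed = 7)
  ra2 <- assign_rates(big, 4, c(1e-4, 3e-4, 1e-3, 3e-3), 1, seed = 8)
  tab <- tabulate(ra2$category, 4)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
  expect_error(assign_rates(tr, 2, c(1e-3, 1e-3), 0.2), "distinct")
  expect_error(assign_rates(tr, 2, c(1e-3, 2e-3), 1.2), "switch_prob")
})

test_that("Poisson branch noise has the right mean and vanishing-noise limit", {
  tr <- simulate_chronogram(6, 50, seed = 9)
  ra <- assign_rates(tr, 2, c(5e-4, 2e-3), 0.2, seed = 10)
  zero <- simulate_phylogram(tr, rep(0, nrow(tr$edge)), 1000, seed = 11)
  expect_true(all(zero$edge.length == 0))
  # Monte-Carlo mean of one branch across seeded replicates
  e <- which.max(tr$edge.length)
  mu <- ra$rate[e] * tr$edge.length[e]
  draws <- vapply(1:1000, function(i)
    simulate_phylogram(tr, ra$rate, 1000, seed = 1000 + i)$edge.length[e],
    numeric(1))
  se <- sqrt(mu / 1000 / 1000)
  expect_lt(abs(mean(draws) - mu), 3 * se + 1e-12)
  # law of large numbers: s -> large recovers r * d within 1% plus
  # three Poisson standard errors (which cover the shortest branches)
  fine <- simulate_phylogram(tr, ra$rate, 1e6, seed = 12)
  expected <- ra$rate * tr$edge.length
  expect_true(all(abs(fine$edge.length - expected) <=
                    0.01 * expected + 3 * sqrt(expected / 1e6)))
})

test_that("tree perturbation is seeded and respects nni_prob = 0", {
  inst <- small_instance(n_tips = 10, seed = 801)
  b0 <- perturb_tree(inst$phylogram, 5, nni_prob = 0, s = inst$s, seed = 13)
  expect_length(b0, 5)
  for (tr in b0)
    expect_true(ape::all.equal.phylo(tr, inst$phylogram,
                                     use.edge.length = FALSE))
  b1 <- perturb_tree(inst$phylogram, 5, nni_prob = 0.5, s = inst$s, seed = 14)
  b2 <- perturb_tree(inst$phylogram, 5, nni_prob = 0.5, s = inst$s, seed = 14)
  expect_identical(vapply(b1, write_newick, character(1)),
                   vapply(b2, write_newick, character(1)))
  # with aggressive NNI at least one replicate changes topology
  expect_true(any(!vapply(b1, ape::all.equal.phylo, logical(1),
                          current = inst$phylogram,
                          use.edge.length = FALSE)))
})

test_that("benchmark profiles produce consistent truth and readable files", {
  toy <- make_benchmark("toy", seed = 6, n_bootstrap = 5)
  expect_length(toy$chronogram$tip.label, 8)
  expect_length(toy$focal_taxa, 3)
  expect_length(toy$points, 3)
  expect_true(is_clade(toy$chronogram, toy$focal_taxa))
  # every calibration box contains the truth it constrains
  for (p in toy$points) {
    node <- mrca_node(toy$chronogram, p$taxa)
    if (p$node_role == "stem")
      node <- toy$chronogram$edge[toy$chronogram$edge[, 2] == node, 1]
    expect_gte(toy$ages[node], p$min_age)
    expect_lte(toy$ages[node], p$max_age)
  }
  dir <- tempfile()
  pl <- make_benchmark("paperlike", seed = 6, dir = dir, n_bootstrap = 3)
  expect_length(pl$chronogram$tip.label, 56)
  expect_length(pl$focal_taxa, 11)
  expect_length(pl$points, 8)
  expect_identical(pl$s, 3754)
  expect_true(all(file.exists(pl$files)))
  # files round trip through the package's own readers
  expect_length(read_tree_file(pl$files[["bootstrap"]]), 3)
  expect_length(read_calibrations(pl$files[["calibrations"]]), 8)
  rt <- read_tree_file(pl$files[["phylogram"]])[[1]]
  expect_setequal(rt$tip.label, pl$chronogram$tip.label)
  expect_error(make_benchmark("nope", seed = 1))
  # different seeds, different data, same schema
  toy2 <- make_benchmark("toy", seed = 7, n_bootstrap = 5)
  expect_false(identical(write_newick(toy$phylogram),
                         write_newick(toy2$phylogram)))
})

test_that("the dating pipeline closes on noiseless generator output", {
  toy <- make_benchmark("toy", seed = 8)
  noiseless <- toy$chronogram
  noiseless$edge.length <- toy$edge_rate * toy$chronogram$edge.length
  root <- length(toy$chronogram$tip.label) + 1
  cons <- data.frame(node = root, min_age = toy$ages[root],
                     max_age = toy$ages[root] + 1e-9, name = "root pin")
  fit <- fit_chronogram(noiseless, cons,
                        clock_config(k = toy$k, s = toy$s, tol = 1e-12))
  idx <- root:(root + toy$chronogram$Nnode - 1)
  expect_lt(max(abs(fit$ages[idx] - toy$ages[idx]) /
                  pmax(toy$ages[idx], 1e-9)), 1e-6)
})
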