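test_that("pl_objective matches closed-form and brute-force re-summation", {
  # two-tip plug-in: b = 0.1, s = 100, root age 10, r = 0.01 -> x = 10,
  # mu = 10, each branch contributes 10*log(10) - 10 - lgamma(11)
  two <- read_newick("(A:0.1,B:0.1);")
  out <- pl_objective(two, ages = c(0, 0, 10), rates = 0.01,
                      assignment = c(1L, 1L),
                      config = clock_config(k = 1, lambda = 0.5, s = 100))
  expect_equal(out$loglik, 2 * (10 * log(10) - 10 - lgamma(11)),
               tolerance = 1e-12)
  expect_equal(out$penalty, 0)          # single category: flat rates
  expect_equal(out$objective, out$loglik - 0.5 * out$penalty)
  # random small instances against a straight-line oracle
  set.seed(404)
  for (i in 1:8) {
    inst <- small_instance(n_tips = 6 + i, seed = 200 + i)
    ages <- inst$ages
    k <- 3
    rates <- sort(runif(k, 1e-4, 5e-3))
    assign <- sample.int(k, nrow(inst$phylogram$edge), replace = TRUE)
    lambda <- runif(1, 0, 2)
    cfg <- clock_config(k = k, lambda = lambda, s = inst$s)
    mine <- pl_objective(inst$phylogram, ages, rates, assign, cfg)
    orac <- oracle_pl_objective(inst$phylogram, ages, rates, assign, lambda,
                                inst$s)
    expect_equal(mine$objective, orac$objective, tolerance = 1e-9)
    expect_equal(mine$penalty, orac$penalty, tolerance = 1e-9)
    expect_equal(mine$objective, mine$loglik - lambda * mine$penalty,
                 tolerance = 1e-9)
  }
})

test_that("degenerate durations are signalled, negative ones are errors", {
  two <- read_newick("(A:0.1,B:0.1);")
  out <- pl_objective(two, ages = c(0, 0, 0), rates = 0.01,
                      assignment = c(1L, 1L), config = clock_config(s = 100))
  expect_identical(out$objective, -Inf)
  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_error(pl_objective(tr, ages = c(0, 0, 0, 1, 2), rates = 0.01,
                            assignment = rep(1L, 4),
                            config = clock_config(s = 100)),
               "parent >= child")
})

test_that("noiseless strict-clock data with a pinned root is recovered exactly", {
  tr <- simulate_chronogram(10, 50, seed = 7)
  rate <- 5e-3
  noiseless <- tr
  noiseless$edge.length <- rate * tr$edge.length
  cons <- data.frame(node = 11L, min_age = 50, max_age = 50, name = "root pin")
  fit <- fit_chronogram(noiseless, cons, clock_config(k = 1, s = 10000,
                                                      tol = 1e-12))
  truth <- node_ages(tr)
  idx <- 11:19
  expect_lt(max(abs(fit$ages[idx] - truth[idx]) / truth[idx]), 1e-6)
  expect_equal(fit$rates, rate, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("two-tip Poisson MLE equals the analytic rate x/T", {
  two <- read_newick("(A:0.1,B:0.1);")
  cons <- data.frame(node = 3L, min_age = 10, max_age = 10, name = "pin")
  fit <- fit_chronogram(two, cons, clock_config(k = 1, s = 100, tol = 1e-12))
  expect_equal(fit$rates, 0.1 / 10, tolerance = 1e-8)
  expect_equal(max(fit$ages), 10)
})

test_that("fits satisfy calibration boxes, ultrametry and the objective identity", {
  inst <- small_instance(seed = 301)
  cons <- resolve_calibrations(inst$phylogram, inst$points)
  for (cfg in list(clock_config(k = 1, s = inst$s),
                   clock_config(k = 2, lambda = 1 / 3, s = inst$s),
                   clock_config(k = 4, lambda = 1, s = inst$s))) {
    fit <- fit_chronogram(inst$phylogram, cons, cfg)
    for (r in seq_len(nrow(cons))) {
      expect_gte(fit$ages[cons$node[r]], cons$min_age[r] - 1e-9)
      expect_lte(fit$ages[cons$node[r]], cons$max_age[r] + 1e-9)
    }
    expect_true(all(fit$tree$edge.length >= -1e-12))
    expect_silent(node_ages(fit$tree))
    expect_equal(fit$objective, fit$loglik - cfg$lambda * fit$penalty,
                 tolerance = 1e-9)
    expect_true(all(fit$edge_rate == fit$rates[fit$edge_category]))
    expect_true(all(fit$rates > 0))
    # tips at age zero
    expect_equal(unname(fit$ages[1:12]), rep(0, 12))
  }
})

test_that("the objective never decreases across k and the k = 1 / k = E limits hold", {
  inst <- small_instance(seed = 302)
  cons <- resolve_calibrations(inst$phylogram, inst$points)
  # k = 1 is the strict clock: zero penalty whatever lambda
  f1 <- fit_chronogram(inst$phylogram, cons,
                       clock_config(k = 1, lambda = 5, s = inst$s))
  expect_equal(f1$penalty, 0)
  expect_length(unique(f1$edge_rate), 1L)
  # lambda = 0, k = number of branches: unpenalized per-branch fitting
  # reaches the saturated Poisson bound at the fitted ages
  E <- nrow(inst$phylogram$edge)
  fE <- fit_chronogram(inst$phylogram, cons,
                       clock_config(k = E, lambda = 0, s = inst$s))
  x <- inst$phylogram$edge.length * inst$s
  saturated <- sum(ifelse(x > 0, x * log(x) - x - lgamma(x + 1), 0))
  expect_equal(fE$loglik, saturated, tolerance = 1e-6)
  # more categories can only improve the unpenalized objective
  f2 <- fit_chronogram(inst$phylogram, cons,
                       clock_config(k = 2, lambda = 0, s = inst$s))
  expect_gte(fE$objective + 1e-6, f2$objective)
  expect_gte(f2$objective + 1e-6, f1$objective)
})

test_that("branch-rate variance is non-increasing in lambda", {
  inst <- small_instance(seed = 303)
  cons <- resolve_calibrations(inst$phylogram, inst$points)
  vars <- vapply(c(0, 0.5, 1, 10, 1000), function(lam) {
    fit <- fit_chronogram(inst$phylogram, cons,
                          clock_config(k = 3, lambda = lam, s = inst$s))
    stats::var(fit$edge_rate)
  }, numeric(1))
  expect_true(all(diff(vars) <= 1e-6))
})

test_that("rescaling calibrations rescales ages and rates (time-unit equivariance)", {
  # evaluation level: the objective is exactly invariant under
  # (ages, rates) -> (c * ages, rates / c) because the log-rate penalty is
  # dimensionless
  inst <- small_instance(seed = 304)
  set.seed(304)
  k <- 2
  rates <- c(4e-4, 1.9e-3)
  assign <- sample.int(k, nrow(inst$phylogram$edge), replace = TRUE)
  for (cc in c(10, 0.37)) {
    a <- pl_objective(inst$phylogram, inst$ages, rates, assign,
                      clock_config(k = k, lambda = 0.7, s = inst$s))
    b <- pl_objective(inst$phylogram, cc * inst$ages, rates / cc, assign,
                      clock_config(k = k, lambda = 0.7, s = inst$s))
    expect_equal(b$objective, a$objective, tolerance = 1e-9)
    expect_equal(b$penalty, a$penalty, tolerance = 1e-9)
  }
  # fit level, with the root age anchored so the weakly identified global
  # time-scale direction cannot drift between runs
  ages <- inst$ages
  root <- length(inst$phylogram$tip.label) + 1
  cons <- resolve_calibrations(inst$phylogram, inst$points)
  cons$min_age[cons$node == root] <- ages[root] - 1e-6
  cons$max_age[cons$node == root] <- ages[root] + 1e-6
  cons10 <- cons
  cons10$min_age <- 10 * cons10$min_age
  cons10$max_age <- 10 * cons10$max_age
  for (cfg in list(clock_config(k = 1, lambda = 0, s = inst$s),
                   clock_config(k = 2, lambda = 0.5, s = inst$s))) {
    fa <- fit_chronogram(inst$phylogram, cons, cfg)
    fb <- fit_chronogram(inst$phylogram, cons10, cfg)
    expect_equal(fb$ages, 10 * fa$ages, tolerance = 1e-5)
    expect_equal(fb$rates, fa$rates / 10, tolerance = 1e-5)
  }
})

test_that("infeasible boxes and unbounded roots are rejected with names", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  cons <- data.frame(node = c(4L, 5L), min_age = c(0, 50),
                     max_age = c(10, 60), name = c("top", "deep-child"))
  expect_error(fit_chronogram(tr, cons, clock_config(s = 100)), "deep-child")
  open_root <- data.frame(node = 5L, min_age = 1, max_age = 2, name = "inner")
  expect_error(fit_chronogram(tr, open_root, clock_config(s = 100)),
               "unbounded")
  expect_error(fit_chronogram(tr, cons[1, ], clock_config(k = 99, s = 100)),
               "exceeds the number of branches")
})

test_that("crown_height returns fitted ages of focal MRCAs", {
  inst <- small_instance(seed = 305)
  cons <- resolve_calibrations(inst$phylogram, inst$points)
  fit <- fit_chronogram(inst$phylogram, cons, clock_config(k = 2, s = inst$s))
  expect_equal(crown_height(fit, inst$phylogram$tip.label), max(fit$ages))
  cherry <- clade_terminals(fit$tree, mrca_node(fit$tree,
                                                fit$tree$tip.label[1:2]))
  expect_equal(crown_height(fit, cherry),
               unname(fit$ages[mrca_node(fit$tree, cherry)]))
  expect_error(crown_height(fit, "nope"), "nope")
})

test_that("seeded fits are deterministic, including restarts", {
  inst <- small_instance(seed = 306)
  cons <- resolve_calibrations(inst$phylogram, inst$points)
  cfg <- clock_config(k = 2, lambda = 1 / 3, s = inst$s, n_starts = 3,
                      seed = 11)
  f1 <- fit_chronogram(inst$phylogram, cons, cfg)
  f2 <- fit_chronogram(inst$phylogram, cons, cfg)
  expect_identical(f1$ages, f2$ages)
  expect_identical(f1$rates, f2$rates)
  expect_identical(f1$objective, f2$objective)
})
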