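test_that("cv_score equals the summation formula and its oracle", {
  expect_equal(cv_score(7, c(7, 7, 7)), 0)
  expect_equal(cv_score(10, c(8, 12)), 0.8)       # (4 + 4) / 10
  set.seed(21)
  for (i in 1:20) {
    och <- runif(1, 0.5, 50)
    pchs <- runif(sample(1:30, 1), 0, 60)
    expect_equal(cv_score(och, pchs), oracle_cv(och, pchs),
                 tolerance = 1e-12)
  }
  expect_error(cv_score(0, c(1, 2)), "positive")
  expect_error(cv_score(-3, c(1, 2)), "positive")
  expect_error(cv_score(5, numeric(0)), "non-empty")
})

test_that("cv_score is permutation-invariant and additive over partitions", {
  set.seed(22)
  och <- 12.5
  pchs <- runif(40, 0, 30)
  expect_equal(cv_score(och, sample(pchs)), cv_score(och, pchs))
  split_at <- 17
  expect_equal(cv_score(och, pchs[1:split_at]) +
                 cv_score(och, pchs[(split_at + 1):40]),
               cv_score(och, pchs), tolerance = 1e-12)
})

test_that("deletion replicates cover all terminals minus forced degeneracies", {
  inst <- small_instance(n_tips = 10, seed = 501)
  focal <- clade_terminals(inst$chronogram,
                           mrca_node(inst$chronogram,
                                     inst$chronogram$tip.label[1:2]))
  reps <- deletion_replicates(inst$phylogram, focal, inst$points)
  n_skip <- nrow(attr(reps, "skipped"))
  expect_identical(length(reps) + n_skip, 10L)
  # every replicate's constraints equal fresh resolution on the pruned tree
  for (rep in reps) {
    pts2 <- lapply(inst$points, function(p) {
      q <- p; q$taxa <- setdiff(p$taxa, rep$label); q
    })
    pts2 <- Filter(function(p) length(p$taxa) >= 2 || p$node_role == "stem",
                   pts2)
    fresh <- suppressWarnings(resolve_calibrations(rep$tree, pts2))
    expect_equal(rep$constraints$node, fresh$node)
    expect_equal(rep$constraints$min_age, fresh$min_age)
    expect_equal(rep$constraints$max_age, fresh$max_age)
  }
})

test_that("deleting a member of a two-terminal focal clade is skipped", {
  tr <- read_newick(paste0("((F1:1,F2:1):7,((((C:2,D:2):2,E:4):1,G:5):1,",
                           "(H:3,I:3):3):2);"))
  focal <- c("F1", "F2")
  pts <- list(calibration_point("root", "crown", tr$tip.label,
                                min_age = 30, max_age = 50))
  reps <- deletion_replicates(tr, focal, pts)
  sk <- attr(reps, "skipped")
  expect_identical(sort(sk$label), sort(focal))
  expect_identical(length(reps), 6L)     # N - 2
  expect_true(all(grepl("focal crown", sk$reason)))
})

test_that("perfectly clock-like data yield a CV of (numerically) zero", {
  tr <- simulate_chronogram(8, 80, seed = 5)
  noiseless <- tr
  noiseless$edge.length <- 8e-4 * tr$edge.length
  pts <- list(calibration_point("root pin", "crown", tr$tip.label,
                                min_age = 80 - 1e-6, max_age = 80 + 1e-6))
  focal <- clade_terminals(tr, mrca_node(tr, tr$tip.label[1:2]))
  cell <- suppressWarnings(
    evaluate_cv_cell(noiseless, focal, pts, k = 2, lambda = 0,
                     config = clock_config(s = 10000)))
  expect_lt(cell$CV, 1e-6)
  expect_identical(cell$M, length(cell$PCH))
})

test_that("grid cells are deterministic and bookkeeping is consistent", {
  inst <- small_instance(n_tips = 8, seed = 502)
  focal <- clade_terminals(inst$chronogram,
                           mrca_node(inst$chronogram,
                                     inst$chronogram$tip.label[1:3]))
  cfg <- clock_config(s = inst$s, tol = 1e-6)
  c1 <- suppressWarnings(
    evaluate_cv_cell(inst$phylogram, focal, inst$points, 2, 1 / 3, cfg))
  c2 <- suppressWarnings(
    evaluate_cv_cell(inst$phylogram, focal, inst$points, 2, 1 / 3, cfg))
  expect_identical(c1$CV, c2$CV)
  expect_identical(c1$PCH, c2$PCH)
  expect_identical(c1$M, length(c1$PCH))
})

test_that("the default grid has 90 cells and argmin equals a full scan", {
  axes <- default_grid_axes()
  expect_identical(length(axes$k) * length(axes$lambda), 90L)
  expect_identical(axes$k, 2:10)
  expect_equal(axes$lambda, (0:9) / 9)
  expect_equal(sprintf("%.2f", axes$lambda[4]), "0.33")
  inst <- small_instance(n_tips = 8, seed = 503)
  focal <- clade_terminals(inst$chronogram,
                           mrca_node(inst$chronogram,
                                     inst$chronogram$tip.label[1:3]))
  surf <- suppressWarnings(
    cv_grid_search(inst$phylogram, focal, inst$points,
                   k_values = c(2, 3), lambda_values = c(0, 0.5, 1),
                   config = clock_config(s = inst$s, tol = 1e-6)))
  expect_identical(nrow(surf$table), 6L)
  full_scan <- surf$table[order(surf$table$CV, surf$table$k,
                                surf$table$lambda), ][1, ]
  expect_equal(surf$argmin$k, full_scan$k)
  expect_equal(surf$argmin$lambda, full_scan$lambda)
  expect_equal(surf$argmin$CV, full_scan$CV)
  # single-cell grid: that cell is the argmin
  one <- suppressWarnings(
    cv_grid_search(inst$phylogram, focal, inst$points,
                   k_values = 2, lambda_values = 1 / 3,
                   config = clock_config(s = inst$s, tol = 1e-6)))
  expect_identical(nrow(one$table), 1L)
  expect_equal(one$argmin$k, 2)
  path <- tempfile(fileext = ".tsv")
  write_cv_surface(surf, path)
  tab <- utils::read.delim(path)
  expect_identical(nrow(tab), 6L)
  expect_true(all(c("k", "lambda", "M", "OCH", "CV", "n_skipped") %in%
                    names(tab)))
})

test_that("CV is driven by prediction stability of the crown height", {
  # a cell whose deletion refits scatter widely must score worse than one
  # whose refits agree; construct both outcomes arithmetically
  stable <- cv_score(10, rep(10, 20) + c(-0.01, 0.01))
  unstable <- cv_score(10, c(rep(10, 18), 30, 2))
  expect_lt(stable, unstable)
  # and CV aggregates per-deletion contributions independently
  expect_equal(cv_score(10, c(10, 10, 30)), cv_score(10, 30))
})
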