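# Shared fixtures and independent oracles, all built in code.

toy_newick <- "((A:1,B:1):1,C:2);"

fixture_calibration_path <- function() {
  system.file("extdata", "didymosphenia_calibrations.tsv", package = "chronocv")
}

# a tree over the packaged calibration table's taxon universe in which all
# eight calibrated clades are recoverable; optionally break the Mediophyceae
# clade (as a parsimony topology might)
study_like_tree <- function(break_medio = FALSE) {
  pts <- read_calibrations(fixture_calibration_path())
  names(pts) <- vapply(pts, `[[`, character(1), "name")
  raphids <- pts[["Raphid pennates crown (6)"]]$taxa
  pinn <- pts[["Pinnularia stem node (7)"]]$taxa
  didymo <- pts[["Didymosphenia crown node (8)"]]$taxa
  core <- setdiff(pts[["Core araphids/raphids split (5)"]]$taxa, raphids)
  pennates <- pts[["Bacillariophyceae crown node (4)"]]$taxa
  basal <- setdiff(pennates, c(core, raphids))
  medio <- pts[["Mediophyceae stem node (3)"]]$taxa
  diatoms <- pts[["Diatoms stem node (1)"]]$taxa
  radial <- setdiff(diatoms, c(pennates, medio))
  if (break_medio) {
    moved <- medio[1]
    medio <- medio[-1]
    radial <- c(radial, moved)
  }
  star <- function(x) paste0("(", paste0(x, ":1", collapse = ","), ")")
  raph_nwk <- paste0("(", star(pinn), ":1,", star(didymo), ":1,",
                     star(setdiff(raphids, c(pinn, didymo))), ":1)")
  nwk <- paste0(
    "(Heterosigma_akashiwo:9,Dictyota_dichotoma:9,(", star(radial), ":2,(",
    star(medio), ":2,(", star(basal), ":2,(", star(core), ":2,",
    raph_nwk, ":2):1):1):1):1);")
  read_newick(nwk)
}

# brute-force MRCA by intersecting root-to-tip paths
oracle_mrca <- function(tree, taxa) {
  ntip <- length(tree$tip.label)
  path_to_root <- function(tip) {
    v <- match(tip, tree$tip.label)
    out <- v
    while (length(p <- tree$edge[tree$edge[, 2] == v, 1])) {
      out <- c(out, p); v <- p
    }
    out
  }
  paths <- lapply(taxa, path_to_root)
  common <- Reduce(intersect, paths)
  common[1]                    # paths are ordered tipward -> rootward
}

# all-pairs terminal path lengths (patristic distances)
oracle_path_lengths <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[order(rownames(d)), order(colnames(d))]
}

# straight-line re-implementation of the penalized objective's three sums
oracle_pl_objective <- function(tree, ages, rates, assignment, lambda, s) {
  E <- nrow(tree$edge)
  ll <- 0
  for (i in seq_len(E)) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    x <- tree$edge.length[i] * s
    ap <- if (p <= length(ages)) ages[p] else 0
    ac <- if (ch <= length(ages)) ages[ch] else 0
    if (ch <= length(tree$tip.label)) ac <- 0
    mu <- rates[assignment[i]] * (ap - ac) * s
    ll <- ll + x * log(mu) - mu - lgamma(x + 1)
  }
  root <- length(tree$tip.label) + 1
  pen <- 0
  for (i in seq_len(E)) {
    p <- tree$edge[i, 1]
    if (p == root) next
    pe <- which(tree$edge[, 2] == p)
    pen <- pen + (log(rates[assignment[i]]) - log(rates[assignment[pe]]))^2
  }
  rc <- which(tree$edge[, 1] == root)
  if (length(rc) >= 2) {
    prs <- utils::combn(rc, 2)
    for (q in seq_len(ncol(prs)))
      pen <- pen + (log(rates[assignment[prs[1, q]]]) -
                      log(rates[assignment[prs[2, q]]]))^2
  }
  list(objective = ll - lambda * pen, loglik = ll, penalty = pen)
}

# loop-and-accumulate CV score
oracle_cv <- function(och, pchs) {
  acc <- 0
  for (p in pchs) acc <- acc + (och - p)^2 / och
  acc
}

# a small noisy benchmark instance shared by several tests
small_instance <- function(n_tips = 12, seed = 101, k = 2,
                           rates = c(5e-4, 2e-3), s = 5000) {
  tr <- simulate_chronogram(n_tips, 80, seed = seed)
  ra <- assign_rates(tr, k, rates, 0.25, seed = seed + 1)
  pg <- simulate_phylogram(tr, ra$rate, s, seed = seed + 2)
  ages <- node_ages(tr)
  root <- n_tips + 1
  pts <- list(
    calibration_point("root", "crown", tr$tip.label,
                      min_age = 0.8 * ages[root], max_age = 1.25 * ages[root],
                      evidence = "secondary"))
  # one mid-depth crown box
  internal <- (n_tips + 2):(n_tips + tr$Nnode)
  v <- internal[which.min(abs(ages[internal] - 0.5 * ages[root]))]
  pts[[2]] <- calibration_point("mid", "crown", clade_terminals(tr, v),
                                min_age = 0.7 * ages[v],
                                max_age = 1.4 * ages[v],
                                evidence = "secondary")
  list(chronogram = tr, ages = ages, phylogram = pg, points = pts,
       rates_true = rates, k = k, s = s, edge_rate = ra$rate,
       edge_category = ra$category)
}
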