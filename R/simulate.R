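# Seeded synthetic benchmarks with known truth: Yule chronograms, a grafted
# shallow focal clade, Markov-switching discrete branch rates, Poisson
# substitution noise, calibration boxes containing the true ages, and
# bootstrap-like tree perturbation (length redraw + random NNIs).

# derive a reproducible substream seed (< 2^31) from a top-level seed and a
# stream name, so independent stages never share a random stream
.substream <- function(seed, name) {
  .hash31(paste(name, as.integer(seed), sep = ":"))
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

#' Simulate an ultrametric chronogram under a Yule process
#'
#' Pure-birth topology from [ape::rphylo()], with node times rescaled so the
#' root age equals `root_age` and all tips sit at age 0.
#'
#' @param n_tips Number of terminals (>= 2).
#' @param root_age Root age in My (> 0).
#' @param seed Integer seed (`NULL` = use the current RNG state).
#' @param tip_prefix Prefix for terminal labels.
#' @return An ultrametric `phylo` with branch lengths in My.
#' @export
simulate_chronogram <- function(n_tips, root_age, seed = NULL,
                                tip_prefix = "t") {
  if (n_tips < 2L) stop("n_tips must be >= 2")
  if (root_age <= 0) stop("root_age must be > 0")
  gen <- function() {
    tr <- ape::rphylo(n_tips, birth = 1, death = 0)
    tr$root.edge <- NULL
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * root_age / depth
    tr$tip.label <- sprintf("%s%02d", tip_prefix, seq_len(n_tips))
    tr
  }
  if (is.null(seed)) gen() else .with_seed(seed, gen())
}

#' Assign discrete rate categories to branches
#'
#' Each branch descending from the root draws its category uniformly; every
#' other branch inherits its parent branch's category with probability
#' `1 - switch_prob` and otherwise redraws uniformly from all k categories.
#' This Markov switching along the tree produces the autocorrelated rate
#' heterogeneity that the smoothing penalty is designed to exploit.
#'
#' @param tree A `phylo`.
#' @param k Number of categories (`k == length(rates)`).
#' @param rates Distinct positive category rates (substitutions/site/My).
#' @param switch_prob Redraw probability in `[0, 1]`.
#' @param seed Integer seed (`NULL` = current RNG state).
#' @return List with `category` (integer per edge, in input edge order) and
#'   `rate` (numeric per edge).
#' @export
assign_rates <- function(tree, k, rates, switch_prob = 0.2, seed = NULL) {
  if (length(rates) != k) stop("k must equal length(rates)")
  if (any(rates <= 0)) stop("rates must be > 0")
  if (anyDuplicated(rates)) stop("rates must be distinct")
  if (!is.numeric(switch_prob) || switch_prob < 0 || switch_prob > 1)
    stop("switch_prob must be in [0, 1]")
  gen <- function() {
    prec <- .tree_prec(tree, 1)
    cat <- integer(prec$E)
    # node preorder guarantees a parent's edge is drawn before its children's
    for (v in prec$preorder) {
      for (e in prec$parent_edges[[v]]) {
        pe <- prec$edge_of_child[v]           # 0 at the root
        if (v == prec$root || pe == 0L) {
          cat[e] <- sample.int(k, 1L)
        } else if (stats::runif(1) < switch_prob) {
          cat[e] <- sample.int(k, 1L)
        } else {
          cat[e] <- cat[pe]
        }
      }
    }
    list(category = cat, rate = rates[cat])
  }
  if (is.null(seed)) gen() else .with_seed(seed, gen())
}

#' Add Poisson substitution noise to a chronogram
#'
#' For each branch of duration `d` (My) with rate `r`, draws a substitution
#' count `x ~ Poisson(r * d * s)` over `s` alignment sites and sets the
#' branch length to `x / s` — exactly the sampling model the dating
#' likelihood assumes.
#'
#' @param tree Chronogram (`phylo`, branch lengths in My).
#' @param edge_rates Numeric vector of per-branch rates (input edge order).
#' @param s Alignment length in sites (>= 1).
#' @param seed Integer seed (`NULL` = current RNG state).
#' @return A `phylo` phylogram (branch lengths in substitutions/site).
#' @export
simulate_phylogram <- function(tree, edge_rates, s, seed = NULL) {
  if (length(edge_rates) != nrow(tree$edge))
    stop("edge_rates must have one entry per edge")
  if (s < 1) stop("s must be >= 1")
  gen <- function() {
    mu <- edge_rates * tree$edge.length * s
    out <- tree
    out$edge.length <- stats::rpois(length(mu), mu) / s
    out
  }
  if (is.null(seed)) gen() else .with_seed(seed, gen())
}

# one random NNI pass: each internal edge (child is a non-root internal
# node) is rearranged with probability nni_prob by swapping a random child
# of the lower node with a random sibling of that node
.random_nni <- function(tree, nni_prob) {
  if (nni_prob <= 0) return(tree)
  edge <- tree$edge
  ntip <- length(tree$tip.label)
  elig <- which(edge[, 2L] > ntip)
  for (e in elig) {
    if (stats::runif(1) >= nni_prob) next
    u <- edge[e, 1L]; v <- edge[e, 2L]
    sibs <- which(edge[, 1L] == u & edge[, 2L] != v)
    kidsv <- which(edge[, 1L] == v)
    if (!length(sibs) || !length(kidsv)) next
    sw <- sibs[[sample.int(length(sibs), 1L)]]
    kv <- kidsv[[sample.int(length(kidsv), 1L)]]
    edge[sw, 1L] <- v
    edge[kv, 1L] <- u
  }
  tree$edge <- edge
  # normalize the representation through a Newick round trip
  read_newick(write_newick(tree))
}

#' Bootstrap-like perturbation of a phylogram
#'
#' Each replicate redraws every branch length by the Poisson mechanism
#' (`x ~ Poisson(b * s)`, new length `x / s`) and then applies a
#' nearest-neighbour interchange to each eligible internal edge with
#' probability `nni_prob`, emulating the topological and length variation of
#' bootstrap tree sets.
#'
#' @param tree A `phylo` phylogram.
#' @param n_replicates Number of replicates (>= 1).
#' @param nni_prob Per-edge NNI probability.
#' @param s Alignment length used for the length redraw.
#' @param seed Integer seed (`NULL` = current RNG state).
#' @param source Label for the resulting tree set.
#' @return A `multiPhylo` of length `n_replicates`.
#' @export
perturb_tree <- function(tree, n_replicates, nni_prob = 0.1, s = 3754,
                         seed = NULL, source = "perturbed") {
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  gen <- function() {
    reps <- vector("list", n_replicates)
    for (i in seq_len(n_replicates)) {
      tr <- tree
      tr$edge.length <- stats::rpois(length(tr$edge.length),
                                     tr$edge.length * s) / s
      reps[[i]] <- .random_nni(tr, nni_prob)
    }
    class(reps) <- "multiPhylo"
    attr(reps, "source") <- source
    reps
  }
  if (is.null(seed)) gen() else .with_seed(seed, gen())
}

# graft a shallow focal subtree in place of one backbone terminal, keeping
# the tree ultrametric (stem length = parent age - focal crown age)
.graft_focal <- function(backbone, focal, attach_tip, stem_length) {
  fmt <- function(x) sprintf("%.12g", x)
  bn <- write_newick(backbone, digits = 12)
  core <- sub(";\\s*$", "", write_newick(focal, digits = 12))
  pat <- paste0("(?<![A-Za-z0-9_])", attach_tip, ":[0-9.eE+-]+")
  rep <- paste0(core, ":", fmt(stem_length))
  out <- sub(pat, rep, bn, perl = TRUE)
  if (identical(out, bn)) stop("graft failed: tip '", attach_tip, "' not found")
  read_newick(out)
}

.benchmark_profiles <- list(
  toy = list(n_background = 6L, n_focal = 3L, root_age = 100, s = 2000,
             k = 2L, rates = c(5e-4, 2e-3), switch_prob = 0.2, n_cal = 3L),
  paperlike = list(n_background = 46L, n_focal = 11L, root_age = 300,
                   s = 3754, k = 2L, rates = c(5e-4, 2e-3),
                   switch_prob = 0.2, n_cal = 8L)
)

#' Build a seeded synthetic benchmark with known truth
#'
#' Simulates a Yule backbone, grafts a shallow focal crown clade (the
#' closely-related-strains analogue), assigns Markov-switching discrete
#' branch rates, draws a Poisson phylogram, writes calibration boxes that
#' contain the true ages by construction, and generates a bootstrap-like
#' tree set.
#'
#' Profiles: `"toy"` (8 terminals, 3 focal, 3 calibrations, s = 2000) for
#' fast smoke tests, and `"paperlike"` (56 terminals, 11 focal, 8
#' calibrations, s = 3754) matching the scale of a multi-locus diatom dating
#' study.
#'
#' @param profile `"toy"` or `"paperlike"`.
#' @param seed Integer top-level seed; all stages draw from named substreams
#'   of it.
#' @param dir Optional output directory; when given, writes `phylogram.nwk`,
#'   `chronogram_true.nwk`, `calibrations.tsv`, `focal_taxa.txt` and
#'   `bootstrap.nwk`.
#' @param n_bootstrap Number of perturbation replicates.
#' @param nni_prob Per-edge NNI probability for the perturbation.
#' @return Object of class `synth_truth`: `chronogram`, `ages`, `phylogram`,
#'   `edge_category`, `edge_rate`, `k`, `rates`, `s`, `focal_taxa`,
#'   `points`, `bootstrap`, `profile`, `seed` (and `files` when written).
#' @export
make_benchmark <- function(profile = c("toy", "paperlike"), seed = 1,
                           dir = NULL, n_bootstrap = 100L, nni_prob = 0.1) {
  profile <- match.arg(profile, names(.benchmark_profiles))
  p <- .benchmark_profiles[[profile]]
  backbone <- simulate_chronogram(p$n_background, p$root_age,
                                  seed = .substream(seed, "backbone"),
                                  tip_prefix = "bg")
  # attach the focal clade below a backbone terminal whose parent is
  # comfortably older than the target crown age
  target <- p$root_age / 30
  ages_bb <- node_ages(backbone)
  ntip_bb <- length(backbone$tip.label)
  parent_age <- vapply(seq_len(ntip_bb), function(i)
    ages_bb[backbone$edge[backbone$edge[, 2L] == i, 1L]], numeric(1))
  cand <- which(parent_age >= 2.5 * target)
  pick <- .with_seed(.substream(seed, "graft"), {
    i <- if (length(cand)) cand[sample.int(length(cand), 1L)] else
      which.max(parent_age)
    crown <- min(target * stats::runif(1, 0.8, 1.2), 0.5 * parent_age[i])
    list(tip = backbone$tip.label[i], crown = crown,
         stem = parent_age[i] - crown)
  })
  focal <- simulate_chronogram(p$n_focal, pick$crown,
                               seed = .substream(seed, "focal"),
                               tip_prefix = "foc")
  chron <- .graft_focal(backbone, focal, pick$tip, pick$stem)
  ages <- node_ages(chron)
  focal_taxa <- focal$tip.label
  ra <- assign_rates(chron, p$k, p$rates, p$switch_prob,
                     seed = .substream(seed, "rates"))
  phylo_gram <- simulate_phylogram(chron, ra$rate, p$s,
                                   seed = .substream(seed, "poisson"))
  points <- .benchmark_calibrations(chron, ages, focal_taxa, p$n_cal,
                                    seed = .substream(seed, "calibrations"))
  # every box must contain the truth it constrains (generator invariant)
  for (pt in points) {
    node <- mrca_node(chron, pt$taxa)
    if (pt$node_role == "stem")
      node <- chron$edge[chron$edge[, 2L] == node, 1L]
    stopifnot(is.na(pt$min_age) || pt$min_age <= ages[node] + 1e-9,
              is.na(pt$max_age) || ages[node] <= pt$max_age + 1e-9)
  }
  boot <- perturb_tree(phylo_gram, n_bootstrap, nni_prob, p$s,
                       seed = .substream(seed, "bootstrap"),
                       source = "synthetic-bootstrap")
  out <- structure(list(chronogram = chron, ages = ages,
                        phylogram = phylo_gram,
                        edge_category = ra$category, edge_rate = ra$rate,
                        k = p$k, rates = p$rates, s = p$s,
                        switch_prob = p$switch_prob,
                        focal_taxa = focal_taxa, points = points,
                        bootstrap = boot, profile = profile, seed = seed),
                   class = "synth_truth")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- c(
      phylogram = file.path(dir, "phylogram.nwk"),
      chronogram = file.path(dir, "chronogram_true.nwk"),
      calibrations = file.path(dir, "calibrations.tsv"),
      focal = file.path(dir, "focal_taxa.txt"),
      bootstrap = file.path(dir, "bootstrap.nwk"))
    writeLines(write_newick(phylo_gram), files[["phylogram"]])
    writeLines(write_newick(chron), files[["chronogram"]])
    write_calibrations(points, files[["calibrations"]])
    writeLines(focal_taxa, files[["focal"]])
    writeLines(vapply(boot, write_newick, character(1)), files[["bootstrap"]])
    out$files <- files
  }
  out
}

# calibration boxes around true node ages: a crown box on the root (which
# also gives the optimizer its required root maximum), a wide box on the
# focal crown (fossil-style asymmetry), and age-stratified boxes on other
# internal nodes, one of which is encoded as a stem point when room allows
.benchmark_calibrations <- function(chron, ages, focal_taxa, n_cal, seed) {
  ntip <- length(chron$tip.label)
  root <- ntip + 1L
  focal_node <- mrca_node(chron, focal_taxa)
  .with_seed(seed, {
    pts <- list(
      calibration_point("root crown", "crown", chron$tip.label,
                        min_age = 0.85 * ages[root],
                        max_age = 1.25 * ages[root], evidence = "secondary"),
      calibration_point("focal crown", "crown", focal_taxa,
                        min_age = 0.5 * ages[focal_node],
                        max_age = 4 * ages[focal_node], evidence = "fossil"))
    inside_focal <- .tips_under(chron, focal_node)
    candidates <- setdiff((ntip + 1L):(ntip + chron$Nnode), c(root, focal_node))
    candidates <- candidates[vapply(candidates, function(v)
      !all(.tips_under(chron, v) %in% inside_focal), logical(1))]
    need <- n_cal - 2L
    if (need > 0L && length(candidates)) {
      o <- candidates[order(ages[candidates], decreasing = TRUE)]
      sel <- o[unique(round(seq(1, length(o), length.out = min(need, length(o)))))]
      for (j in seq_along(sel)) {
        v <- sel[j]
        taxa <- clade_terminals(chron, v)
        par <- chron$edge[chron$edge[, 2L] == v, 1L]
        as_stem <- j == 2L && par != root
        node_age <- if (as_stem) ages[par] else ages[v]
        pts[[length(pts) + 1L]] <- calibration_point(
          name = sprintf("node%02d %s", v, if (as_stem) "stem" else "crown"),
          node_role = if (as_stem) "stem" else "crown", taxa = taxa,
          min_age = stats::runif(1, 0.6, 0.85) * node_age,
          max_age = stats::runif(1, 1.2, 1.6) * node_age,
          evidence = "secondary")
      }
    }
    pts
  })
}

#' @export
print.synth_truth <- function(x, ...) {
  cat(sprintf(
    "synth_truth '%s' (seed %s): %d terminals (%d focal), k = %d, s = %g\n",
    x$profile, format(x$seed), length(x$chronogram$tip.label),
    length(x$focal_taxa), x$k, x$s))
  cat(sprintf("  root age %.4g My, focal crown %.4g My, %d calibrations, %d bootstrap trees\n",
              max(x$ages), x$ages[mrca_node(x$chronogram, x$focal_taxa)],
              length(x$points), length(x$bootstrap)))
  invisible(x)
}
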