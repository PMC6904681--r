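# Penalized-likelihood dating under a discrete relaxed clock.
#
# Model: for branch i with observed length b_i (substitutions/site) on an
# alignment of s sites, the expected substitution count is
# mu_i = r_{c(i)} * d_i * s, where d_i is the branch duration (My) implied by
# the node ages, r_1..r_k are k shared rate categories and c(i) assigns the
# branch to a category. The fit maximizes
#   log L - lambda * penalty,
# log L = sum_i [ x_i log(mu_i) - mu_i - lgamma(x_i + 1) ] with x_i = b_i * s
# treated as a continuous Poisson count, and
# penalty = sum over non-root branches of
#   (log r_{c(i)} - log r_{c(parent branch)})^2
# plus all pairwise terms among the root's child branches. The log scale
# makes the penalty dimensionless (invariant to the time unit), so lambda
# weights the roughness of rate *ratios*, not of absolute rates. Node ages
# live in calibration boxes [min, max] propagated over the tree.

#' Clock configuration for penalized-likelihood dating
#'
#' @param k Number of discrete rate categories (integer >= 1).
#' @param lambda Penalty weight on rate changes between adjacent branches
#'   (>= 0). `lambda = 0` leaves category rates unpenalized; large `lambda`
#'   with `k > 1` pulls the categories together towards a strict clock.
#' @param s Alignment length in sites, used to convert branch lengths
#'   (substitutions/site) into expected substitution counts. Default 3754.
#' @param max_iter Maximum block-coordinate cycles.
#' @param tol Relative objective-change convergence threshold.
#' @param n_starts Number of seeded restarts (first start is deterministic,
#'   later starts jitter the initial ages by ±10%).
#' @param seed Integer seed for restart jitter (`NULL` = no reseeding; with
#'   `n_starts = 1` no randomness is consumed at all).
#' @param rate_floor Lower bound for category rates.
#' @param ages_maxit Maximum L-BFGS-B iterations per age update.
#' @param init_ages Optional warm start: numeric vector of node ages indexed
#'   by node id of the tree being fitted (NA entries are interpolated).
#' @param init_rates Optional warm start: category rates from a related fit
#'   (e.g. the reference tree's), used to seed the category split.
#' @param ladder_ages Optional cached strict-clock (k = 1) ages for this
#'   tree, reused as the cold-start base instead of refitting k = 1 (the
#'   ladder fit does not depend on k or lambda, so grid scans compute it
#'   once per tree).
#' @param lean Use the reduced candidate set (k-means and EM category
#'   splits, no skewed splits, no polish pass); the default for the many
#'   per-replicate fits inside grid scans, where speed matters and the
#'   ladder base is already good.
#' @return An object of class `clock_config`.
#' @export
clock_config <- function(k = 2L, lambda = 0, s = 3754L, max_iter = 500L,
                         tol = 1e-8, n_starts = 1L, seed = NULL,
                         rate_floor = 1e-12, ages_maxit = 100L,
                         init_ages = NULL, init_rates = NULL,
                         ladder_ages = NULL, lean = FALSE) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be an integer >= 1")
  if (!is.numeric(lambda) || lambda < 0) stop("lambda must be >= 0")
  s <- as.numeric(s)
  if (is.na(s) || s < 1) stop("s (alignment length) must be >= 1")
  structure(list(k = k, lambda = as.numeric(lambda), s = s,
                 max_iter = as.integer(max_iter), tol = tol,
                 n_starts = as.integer(n_starts), seed = seed,
                 rate_floor = rate_floor, ages_maxit = as.integer(ages_maxit),
                 init_ages = init_ages, init_rates = init_rates,
                 ladder_ages = ladder_ages, lean = isTRUE(lean)),
            class = "clock_config")
}

# ---- internal tree precomputation -----------------------------------------

.tree_prec <- function(tree, s) {
  E <- nrow(tree$edge)
  parent <- tree$edge[, 1L]; child <- tree$edge[, 2L]
  ntip <- length(tree$tip.label)
  N <- ntip + tree$Nnode
  root <- ntip + 1L
  b <- tree$edge.length
  x <- b * s
  edge_of_child <- integer(N)
  edge_of_child[child] <- seq_len(E)
  pe <- ifelse(parent == root, NA_integer_, edge_of_child[parent])
  nonroot <- which(parent != root)
  ii <- nonroot; jj <- pe[nonroot]
  rc <- which(parent == root)
  if (length(rc) >= 2L) {
    cmb <- utils::combn(rc, 2L)
    ii <- c(ii, cmb[1L, ]); jj <- c(jj, cmb[2L, ])
  }
  # per-edge penalty-neighbour degree and adjacency (for assignment step)
  deg <- tabulate(c(ii, jj), nbins = E)
  # preorder of internal nodes (root first), parent_of, internal children
  kids <- split(child, parent)
  parent_of <- integer(N); parent_of[child] <- parent
  pre <- integer(tree$Nnode); pre[1L] <- root; head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- pre[head]
    for (u in kids[[as.character(v)]]) if (u > ntip) { tail <- tail + 1L; pre[tail] <- u }
    head <- head + 1L
  }
  fidx <- integer(N); fidx[pre] <- seq_along(pre)
  parent_edges <- lapply(seq_len(N), function(v) which(parent == v))
  pa_idx <- unique(parent)
  pf <- match(parent, pa_idx)
  structure(list(tree = tree, E = E, parent = parent, child = child,
                 ntip = ntip, N = N, root = root, s = s, b = b, x = x,
                 lgx = sum(lgamma(x + 1)), ii = ii, jj = jj, deg = deg,
                 preorder = pre, parent_of = parent_of, fidx = fidx,
                 parent_edges = parent_edges, edge_of_child = edge_of_child,
                 pa_idx = pa_idx, pf = pf),
            class = "pl_prec")
}

# ---- calibration-box propagation ------------------------------------------

# Effective per-node age boxes: tips are pinned at 0, constraint minima
# propagate rootwards (a parent is at least as old as any descendant's
# minimum), constraint maxima propagate tipwards. Infeasible boxes raise an
# error naming the constraints that collide.
.node_bounds <- function(prec, constraints) {
  N <- prec$N; ntip <- prec$ntip
  lo <- numeric(N); hi <- rep(Inf, N)
  lo_src <- rep("tip age 0", N); hi_src <- rep("(none)", N)
  hi[seq_len(ntip)] <- 0
  if (nrow(constraints)) {
    for (r in seq_len(nrow(constraints))) {
      v <- constraints$node[r]
      if (constraints$min_age[r] > lo[v]) {
        lo[v] <- constraints$min_age[r]; lo_src[v] <- constraints$name[r]
      }
      if (constraints$max_age[r] < hi[v]) {
        hi[v] <- constraints$max_age[r]; hi_src[v] <- constraints$name[r]
      }
    }
  }
  # minima rootwards (children before parents)
  for (v in rev(prec$preorder)) {
    p <- prec$parent_of[v]
    if (v != prec$root && lo[v] > lo[p]) { lo[p] <- lo[v]; lo_src[p] <- lo_src[v] }
  }
  # maxima tipwards
  for (v in prec$preorder) {
    p <- prec$parent_of[v]
    if (v != prec$root && hi[p] < hi[v]) { hi[v] <- hi[p]; hi_src[v] <- hi_src[p] }
  }
  bad <- which(lo > hi)
  if (length(bad))
    stop(sprintf(
      "infeasible calibration box at node %d: minimum %.6g from '%s' exceeds maximum %.6g from '%s'",
      bad[1L], lo[bad[1L]], lo_src[bad[1L]], hi[bad[1L]], hi_src[bad[1L]]))
  list(lo = lo, hi = hi, lo_src = lo_src, hi_src = hi_src)
}

# ---- proportional-depth transform -----------------------------------------

# Internal node v gets age t_v = lo_v + f_v * (min(t_parent, hi_v) - lo_v)
# with f_v in [0, 1]; the root uses its own finite box. Parent >= child is
# implicit because lo_parent >= lo_child after propagation.
.f_to_ages <- function(prec, bnd, f) {
  pre <- prec$preorder; po <- prec$parent_of
  lo <- bnd$lo; hi <- bnd$hi; root <- prec$root
  t <- numeric(prec$N)
  cap <- numeric(prec$N)
  for (i in seq_along(pre)) {        # fidx[pre[i]] == i by construction
    v <- pre[i]
    cp <- if (v == root) hi[v] else {
      tp <- t[po[v]]; hv <- hi[v]; if (tp < hv) tp else hv
    }
    cap[v] <- cp
    t[v] <- lo[v] + f[i] * (cp - lo[v])
  }
  list(t = t, cap = cap)
}

.ages_to_f <- function(prec, bnd, ages) {
  f <- numeric(length(prec$preorder))
  t <- numeric(prec$N)
  for (v in prec$preorder) {
    cp <- if (v == prec$root) bnd$hi[v] else min(t[prec$parent_of[v]], bnd$hi[v])
    width <- cp - bnd$lo[v]
    fv <- if (width > 0) (ages[v] - bnd$lo[v]) / width else 0.5
    fv <- min(max(fv, 1e-4), 1 - 1e-4)
    f[prec$fidx[v]] <- fv
    t[v] <- bnd$lo[v] + fv * width
  }
  f
}

# ---- objective and gradient -----------------------------------------------

.obj_eval <- function(prec, t, rates, assign, lambda, dfloor) {
  d <- t[prec$parent] - t[prec$child]
  de <- d; de[de < dfloor] <- dfloor
  rr <- rates[assign]
  mu <- rr * de * prec$s
  ll <- sum(prec$x * log(mu) - mu) - prec$lgx
  lr <- log(rr)
  pen <- sum((lr[prec$ii] - lr[prec$jj])^2)
  list(obj = ll - lambda * pen, ll = ll, pen = pen,
       d = d, de = de, mu = mu, rr = rr)
}

# gradient of the objective w.r.t. the proportional-depth coordinates f
.grad_f <- function(prec, bnd, f, tt, rates, assign, dfloor) {
  t <- tt$t; cap <- tt$cap
  parent <- prec$parent; child <- prec$child
  d <- t[parent] - t[child]
  clamped <- d <= dfloor
  de <- d; de[clamped] <- dfloor
  rr <- rates[assign]
  mu <- rr * de * prec$s
  w <- (prec$x / mu - 1) * rr * prec$s
  w[clamped] <- 0
  gt <- numeric(prec$N)
  gt[child] <- -w                        # each child has exactly one edge
  ps <- rowsum(w, prec$pf, reorder = FALSE)  # per-parent sums, C level
  gt[prec$pa_idx] <- gt[prec$pa_idx] + ps[, 1L]
  # adjoint pass through the recursive transform, reverse preorder
  pre <- prec$preorder; po <- prec$parent_of
  lo <- bnd$lo; hi <- bnd$hi; root <- prec$root
  a <- numeric(prec$N)
  gf <- numeric(length(pre))
  for (i in rev(seq_along(pre))) {
    v <- pre[i]
    av <- a[v] + gt[v]
    a[v] <- av
    if (v != root) {
      p <- po[v]
      if (t[p] < hi[v]) a[p] <- a[p] + av * f[i]
    }
    gf[i] <- av * (cap[v] - lo[v])
  }
  gf
}

# ---- block updates --------------------------------------------------------

# category reassignment: Jacobi sweeps over score(edge, category), accepted
# only while the full objective does not decrease; ties -> lowest index
.update_assign <- function(prec, t, rates, assign, lambda, dfloor, max_sweeps = 5L) {
  k <- length(rates)
  if (k == 1L) return(assign)
  d <- t[prec$parent] - t[prec$child]
  de <- pmax(d, dfloor)
  llmat <- outer(prec$x, log(rates)) - outer(de * prec$s, rates)
  cur <- .obj_eval(prec, t, rates, assign, lambda, dfloor)$obj
  lrates <- log(rates)
  for (sw in seq_len(max_sweeps)) {
    lr <- lrates[assign]
    S <- numeric(prec$E)           # sum of neighbour log-rates per edge
    for (p in seq_along(prec$ii)) {
      S[prec$ii[p]] <- S[prec$ii[p]] + lr[prec$jj[p]]
      S[prec$jj[p]] <- S[prec$jj[p]] + lr[prec$ii[p]]
    }
    score <- llmat - lambda * (outer(prec$deg, lrates^2) - 2 * outer(S, lrates))
    new_assign <- max.col(score, ties.method = "first")
    if (all(new_assign == assign)) break
    new_obj <- .obj_eval(prec, t, rates, new_assign, lambda, dfloor)$obj
    if (new_obj < cur - 1e-12 * (abs(cur) + 1)) break   # reject, keep current
    assign <- new_assign; cur <- new_obj
  }
  assign
}

# exact per-category rate update (Gauss-Seidel over categories); in
# u = log r_m the objective slice is
#   A u - B exp(u) - lambda (a u^2 - 2 c u) + const,
# strictly concave with derivative h(u) = A - B exp(u) - 2 lambda (a u - c)
# strictly decreasing, so the unique root of h is the global slice maximum.
.update_rates <- function(prec, t, rates, assign, lambda, dfloor, floor) {
  de <- pmax(t[prec$parent] - t[prec$child], dfloor)
  ci <- assign[prec$ii]; cj <- assign[prec$jj]
  lr <- log(rates)
  for (m in seq_along(rates)) {
    sel <- assign == m
    if (!any(sel)) next
    A <- sum(prec$x[sel])
    B <- sum(de[sel]) * prec$s
    if (B <= 0) next
    one <- xor(ci == m, cj == m)
    a <- sum(one)
    cc <- if (a) sum(ifelse(ci[one] == m, lr[cj[one]], lr[ci[one]])) else 0
    if (lambda == 0 || a == 0) {
      rates[m] <- max(A / B, floor)
    } else {
      h <- function(u) A - B * exp(u) - 2 * lambda * (a * u - cc)
      u0 <- log(max(A / B, floor))
      lo <- u0; hi <- u0
      while (h(lo) < 0 && lo > -745) lo <- lo - 2
      while (h(hi) > 0 && hi < 700) hi <- hi + 2
      u <- if (h(lo) < 0) lo else if (h(hi) > 0) hi else
        stats::uniroot(h, c(lo, hi), tol = 1e-12)$root
      rates[m] <- max(exp(u), floor)
    }
    lr[m] <- log(rates[m])
  }
  rates
}

# joint update of ages (proportional-depth coordinates f) and log category
# rates u by one L-BFGS-B run; optimizing them together avoids the zigzag
# along the rate-time compensation ridge that alternating updates suffer
.update_ages_rates <- function(prec, bnd, f, u, assign, lambda, dfloor,
                               maxit, factr, rate_floor) {
  m <- length(f); k <- length(u)
  pen_ii <- assign[prec$ii]; pen_jj <- assign[prec$jj]
  # optim evaluates fn and gr back to back at the same point: cache the
  # age transform between the two
  last_par <- NULL; last_tt <- NULL
  ages_at <- function(fv) {
    if (is.null(last_par) || !identical(fv, last_par)) {
      last_par <<- fv; last_tt <<- .f_to_ages(prec, bnd, fv)
    }
    last_tt
  }
  fn <- function(par) {
    tt <- ages_at(par[seq_len(m)])
    .obj_eval(prec, tt$t, exp(par[m + seq_len(k)]), assign, lambda, dfloor)$obj
  }
  cat_idx <- split(seq_len(prec$E), factor(assign, levels = seq_len(k)))
  pen_i_of <- lapply(seq_len(k), function(j) which(pen_ii == j))
  pen_j_of <- lapply(seq_len(k), function(j) which(pen_jj == j))
  gr <- function(par) {
    fv <- par[seq_len(m)]; uv <- par[m + seq_len(k)]
    rates <- exp(uv)
    tt <- ages_at(fv)
    gf <- .grad_f(prec, bnd, fv, tt, rates, assign, dfloor)
    t <- tt$t
    de <- t[prec$parent] - t[prec$child]
    de[de < dfloor] <- dfloor
    mu <- rates[assign] * de * prec$s
    resid <- prec$x - mu
    gu <- vapply(cat_idx, function(ix) sum(resid[ix]), numeric(1))
    if (lambda > 0 && k > 1L) {
      dpen <- 2 * (uv[pen_ii] - uv[pen_jj])
      for (j in seq_len(k)) {
        gu[j] <- gu[j] - lambda *
          (sum(dpen[pen_i_of[[j]]]) - sum(dpen[pen_j_of[[j]]]))
      }
    }
    c(gf, gu)
  }
  par0 <- c(f, u)
  cur <- fn(par0)
  res <- tryCatch(
    stats::optim(par0, fn, gr, method = "L-BFGS-B",
                 lower = c(rep(0, m), rep(log(rate_floor), k)),
                 upper = c(rep(1, m), rep(Inf, k)),
                 control = list(fnscale = -1, maxit = maxit, factr = factr)),
    error = function(e) NULL)
  if (!is.null(res) && is.finite(res$value) && res$value >= cur)
    list(f = res$par[seq_len(m)], u = res$par[m + seq_len(k)], obj = res$value)
  else list(f = f, u = u, obj = cur)
}

# ---- initialization -------------------------------------------------------

# node "height" in edge counts above the tallest descendant tip
.node_levels <- function(prec) {
  h <- numeric(prec$N)
  for (v in rev(prec$preorder)) {
    pe <- prec$parent_edges[[v]]
    h[v] <- 1 + max(h[prec$child[pe]])
  }
  h
}

.init_ages <- function(prec, bnd, init_ages = NULL) {
  ages <- numeric(prec$N)
  root <- prec$root
  root_mid <- (bnd$lo[root] + bnd$hi[root]) / 2
  h <- .node_levels(prec)
  ages[prec$preorder] <- root_mid * h[prec$preorder] / h[root]
  if (!is.null(init_ages)) {
    known <- which(!is.na(init_ages[seq_len(prec$N)]))
    known <- known[known > prec$ntip]
    ages[known] <- init_ages[known]
  }
  .ages_to_f(prec, bnd, ages)
}

# winsorized per-branch rate estimates at given ages; a single near-zero
# initial duration must not seed a runaway rate category
.rhat_at <- function(prec, t, floor) {
  de <- pmax(t[prec$parent] - t[prec$child], 1e-12)
  rhat <- pmax(prec$b / de, floor)
  r0 <- max(sum(prec$b) / sum(de), floor)
  pmin(pmax(rhat, r0 / 10), r0 * 10)
}

.finish_split <- function(rhat, assign, k, floor) {
  rates <- vapply(seq_len(k), function(m) {
    v <- rhat[assign == m]
    if (length(v)) mean(v) else mean(rhat)
  }, numeric(1))
  rates <- sort(pmax(rates, floor))
  for (m in seq_len(k)[-1]) if (rates[m] <= rates[m - 1])
    rates[m] <- rates[m - 1] * (1 + 1e-6)
  # reassign to nearest category on the log scale so assignment and the
  # sorted rates stay coherent
  assign <- max.col(-abs(outer(log(rhat), log(rates), "-")),
                    ties.method = "first")
  list(rates = rates, assign = assign)
}

# rank split of rhat into chunks of the given proportions (slowest first)
.split_by_props <- function(rhat, props, floor) {
  k <- length(props)
  E <- length(rhat)
  sizes <- pmax(1L, round(props / sum(props) * E))
  while (sum(sizes) > E) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
  while (sum(sizes) < E) sizes[which.min(sizes)] <- sizes[which.min(sizes)] + 1L
  grp <- rep.int(seq_len(k), sizes)
  assign <- integer(E)
  assign[order(rhat)] <- grp
  .finish_split(rhat, assign, k, floor)
}

# Poisson-mixture EM on branch counts with exposures d_i * s at fixed ages:
# unlike rank/k-means splits of rate estimates, EM weights each branch by
# its information content, which matters when many branches are short
.init_rates_em <- function(prec, t, k, floor) {
  de <- pmax(t[prec$parent] - t[prec$child], 1e-12)
  expo <- de * prec$s
  x <- prec$x
  seed_split <- .init_rates(prec, t, k, floor)
  r <- seed_split$rates
  pi_m <- pmax(tabulate(seed_split$assign, k) / prec$E, 1e-3)
  for (it in 1:60) {
    lg <- outer(x, log(r)) - outer(expo, r) +
      matrix(log(pi_m), prec$E, k, byrow = TRUE)
    lg <- lg - apply(lg, 1L, max)
    g <- exp(lg); g <- g / rowSums(g)
    r_new <- pmax(colSums(g * x) / pmax(colSums(g * expo), 1e-300), floor)
    pi_new <- pmax(colMeans(g), 1e-6)
    if (max(abs(log(r_new / r))) < 1e-8) { r <- r_new; pi_m <- pi_new; break }
    r <- r_new; pi_m <- pi_new
  }
  o <- order(r)
  r <- r[o]
  for (m in seq_len(k)[-1]) if (r[m] <= r[m - 1]) r[m] <- r[m - 1] * (1 + 1e-6)
  assign <- max.col(lg[, o, drop = FALSE], ties.method = "first")
  list(rates = r, assign = assign)
}

# deterministic 1-D k-means (Lloyd) on log rate estimates, seeded at evenly
# spaced quantiles: category proportions adapt to the data
.init_rates <- function(prec, t, k, floor) {
  rhat <- .rhat_at(prec, t, floor)
  if (k == 1L) {
    de <- pmax(t[prec$parent] - t[prec$child], 1e-12)
    return(list(rates = max(sum(prec$b) / sum(de), floor),
                assign = rep(1L, prec$E)))
  }
  lr <- log(rhat)
  centers <- stats::quantile(lr, (seq_len(k) - 0.5) / k, names = FALSE,
                             type = 7)
  centers <- centers + seq_len(k) * 1e-9          # force distinct
  for (it in 1:25) {
    assign <- max.col(-abs(outer(lr, centers, "-")), ties.method = "first")
    new_centers <- vapply(seq_len(k), function(m) {
      v <- lr[assign == m]
      if (length(v)) mean(v) else centers[m]
    }, numeric(1))
    if (max(abs(new_centers - centers)) < 1e-10) break
    centers <- new_centers
  }
  .finish_split(rhat, assign, k, floor)
}

# ---- main fit -------------------------------------------------------------

#' Fit a chronogram by penalized likelihood
#'
#' Maximizes the penalized Poisson likelihood of a discrete-rate clock (see
#' the package vignette) over node ages, category rates and branch-category
#' assignments by block-coordinate ascent: (i) each branch is reassigned to
#' its best category (ties to the lowest index), (ii) category rates are
#' updated by an exact 1-D concave maximization, (iii) ages are updated by
#' L-BFGS-B in a proportional-depth parameterization that keeps every
#' calibration box and every parent-older-than-child ordering satisfied by
#' construction. The best of `n_starts` seeded restarts is returned.
#'
#' @param tree A rooted `phylo` phylogram (branch lengths in
#'   substitutions/site, >= 2 terminals).
#' @param constraints Resolved constraints from [resolve_calibrations()];
#'   at least one constraint must bound the root's age from above.
#' @param config A [clock_config()].
#' @return An object of class `chronogram_fit`: the fitted ultrametric
#'   `tree` (branch lengths in My), `ages` (vector over node ids),
#'   `rates` (category rates, substitutions/site/My), `edge_category`,
#'   `edge_rate`, `objective`, `loglik`, `penalty`, `converged`,
#'   `iterations`, plus the `k`, `lambda`, `s` used.
#' @export
fit_chronogram <- function(tree, constraints, config = clock_config()) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) stop("tree must have >= 2 terminals")
  prec <- .tree_prec(tree, config$s)
  if (config$k > prec$E)
    stop("k (", config$k, ") exceeds the number of branches (", prec$E, ")")
  bnd <- .node_bounds(prec, constraints)
  if (!is.finite(bnd$hi[prec$root]))
    stop("the root age is unbounded above: add a calibration with a maximum ",
         "age on the root (or a clade spanning all terminals)")
  dfloor <- 1e-8 * bnd$hi[prec$root]
  lambda <- config$lambda; k <- config$k
  init_ages <- config$init_ages
  if (k > 1L && is.null(init_ages)) {
    # clock ladder: a strict-clock (k = 1) fit provides well-identified
    # starting ages; cold-starting the relaxed model from depth
    # interpolation is prone to distant local modes
    if (!is.null(config$ladder_ages)) {
      init_ages <- config$ladder_ages
    } else {
      cfg1 <- config
      cfg1$k <- 1L; cfg1$n_starts <- 1L
      init_ages <- fit_chronogram(tree, constraints, cfg1)$ages
    }
  }
  f0 <- .init_ages(prec, bnd, init_ages)

  factr <- min(max(10, config$tol * 1e12), 1e7)
  run_start <- function(f, ini = NULL) {
    tt <- .f_to_ages(prec, bnd, f)
    if (is.null(ini)) ini <- .init_rates(prec, tt$t, k, config$rate_floor)
    rates <- ini$rates; assign <- ini$assign
    obj <- .obj_eval(prec, tt$t, rates, assign, lambda, dfloor)$obj
    converged <- FALSE; it <- 0L
    while (it < config$max_iter) {
      it <- it + 1L
      assign <- .update_assign(prec, tt$t, rates, assign, lambda, dfloor)
      rates <- .update_rates(prec, tt$t, rates, assign, lambda, dfloor,
                             config$rate_floor)
      upd <- .update_ages_rates(prec, bnd, f, log(rates), assign, lambda,
                                dfloor, config$ages_maxit, factr,
                                config$rate_floor)
      f <- upd$f; rates <- exp(upd$u)
      tt <- .f_to_ages(prec, bnd, f)
      new_obj <- upd$obj
      if (abs(new_obj - obj) < config$tol * (abs(obj) + 1e-12) &&
          new_obj >= obj) {
        obj <- new_obj; converged <- TRUE; break
      }
      obj <- new_obj
    }
    list(f = f, t = tt$t, rates = rates, assign = assign, obj = obj,
         converged = converged, iterations = it)
  }

  cold <- is.null(config$init_ages)
  warm_rates <- !is.null(config$init_rates) &&
    length(config$init_rates) == k && k > 1L
  if (config$lean && cold && k > 1L) {
    # lean scans: EM split as the single base candidate, plus the seeded
    # split when a related fit's rates are available
    t0 <- .f_to_ages(prec, bnd, f0)$t
    best <- run_start(f0, .init_rates_em(prec, t0, k, config$rate_floor))
    if (warm_rates) {
      rhat0 <- .rhat_at(prec, t0, config$rate_floor)
      r0 <- sort(pmax(config$init_rates, config$rate_floor))
      cand <- run_start(f0, .finish_split(rhat0, max.col(
        -abs(outer(log(rhat0), log(r0), "-")), ties.method = "first"),
        k, config$rate_floor))
      if (cand$obj > best$obj) best <- cand
    }
  } else if (warm_rates && !cold) {
    # warm starts seeded from a related fit: keep its category rates,
    # assigning each branch to the nearest category on the log scale
    t0 <- .f_to_ages(prec, bnd, f0)$t
    rhat0 <- .rhat_at(prec, t0, config$rate_floor)
    r0 <- sort(pmax(config$init_rates, config$rate_floor))
    assign0 <- max.col(-abs(outer(log(rhat0), log(r0), "-")),
                       ties.method = "first")
    best <- run_start(f0, list(rates = r0, assign = assign0))
  } else {
    best <- run_start(f0)
  }
  if (k > 1L && cold && !config$lean) {
    # the category split is a combinatorial choice with sticky local modes:
    # on cold fits try several deterministic splits and keep the best
    t0 <- .f_to_ages(prec, bnd, f0)$t
    rhat0 <- .rhat_at(prec, t0, config$rate_floor)
    props <- 0.25^(seq_len(k) - 1L)
    inis <- list(.init_rates_em(prec, t0, k, config$rate_floor),
                 .split_by_props(rhat0, props, config$rate_floor),
                 .split_by_props(rhat0, rev(props), config$rate_floor))
    if (warm_rates) {
      r0 <- sort(pmax(config$init_rates, config$rate_floor))
      inis <- c(inis, list(.finish_split(rhat0, max.col(
        -abs(outer(log(rhat0), log(r0), "-")), ties.method = "first"),
        k, config$rate_floor)))
    }
    for (ini in inis) {
      cand <- run_start(f0, ini)
      if (cand$obj > best$obj) best <- cand
    }
    # polish pass: re-derive the category split at the fitted ages and refit
    for (rep in 1:2) {
      fb <- .ages_to_f(prec, bnd, best$t)
      tb <- .f_to_ages(prec, bnd, fb)$t
      cand <- run_start(fb, .init_rates_em(prec, tb, k, config$rate_floor))
      if (cand$obj > best$obj + config$tol * (abs(best$obj) + 1e-12))
        best <- cand
      else break
    }
  }
  if (config$n_starts > 1L) {
    if (!is.null(config$seed)) {
      old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
      set.seed(config$seed)
    }
    for (st in seq_len(config$n_starts - 1L)) {
      fj <- pmin(pmax(f0 * stats::runif(length(f0), 0.85, 1.15), 0), 1)
      cand <- run_start(fj)
      if (cand$obj > best$obj) best <- cand
      if (k > 1L) {
        tj <- .f_to_ages(prec, bnd, fj)$t
        cand <- run_start(fj, .init_rates_em(prec, tj, k, config$rate_floor))
        if (cand$obj > best$obj) best <- cand
      }
    }
  }

  t <- best$t
  terms <- .obj_eval(prec, t, best$rates, best$assign, lambda, dfloor)
  chron <- tree
  chron$edge.length <- t[prec$parent] - t[prec$child]
  structure(list(tree = chron, ages = t, rates = best$rates,
                 edge_category = best$assign,
                 edge_rate = best$rates[best$assign],
                 objective = terms$obj, loglik = terms$ll,
                 penalty = terms$pen, converged = best$converged,
                 iterations = best$iterations,
                 k = k, lambda = lambda, s = config$s,
                 constraints = constraints),
            class = "chronogram_fit")
}

#' @export
print.chronogram_fit <- function(x, ...) {
  cat(sprintf(
    "chronogram_fit: %d terminals, k = %d, lambda = %.4g, s = %g\n",
    length(x$tree$tip.label), x$k, x$lambda, x$s))
  cat(sprintf("  root age %.4g My; objective %.6g (loglik %.6g, penalty %.6g)\n",
              max(x$ages), x$objective, x$loglik, x$penalty))
  cat(sprintf("  rates: %s\n", paste(signif(x$rates, 4), collapse = ", ")))
  cat(sprintf("  %s after %d cycles\n",
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Penalized-likelihood objective of a discrete-rate clock
#'
#' Evaluates the objective at given ages, category rates and branch
#' assignments, without any optimization:
#' `loglik = sum_i [x_i log(mu_i) - mu_i - lgamma(x_i + 1)]` with
#' `x_i = b_i * s` and `mu_i = r_(c(i)) * d_i * s`;
#' `penalty = sum over non-root branches of
#' (log r_(c(i)) - log r_(c(parent branch)))^2` plus all pairwise terms
#' among the root's child branches; `objective = loglik - lambda * penalty`.
#' The log scale makes the penalty invariant to the time unit, so `lambda`
#' weights rate *ratios* between adjacent branches. Useful for audits and as
#' the contract the optimizer maximizes. Branch durations equal to zero with
#' a positive substitution count give `objective = -Inf` (signalled, not an
#' error); negative durations are an error.
#'
#' @param tree A rooted `phylo` phylogram.
#' @param ages Numeric vector of node ages indexed by node id (tips may be
#'   omitted or 0).
#' @param rates Positive category rates `r_1..r_k`.
#' @param assignment Integer vector over edges (rows of `tree$edge`) giving
#'   each branch's category in `1..k`.
#' @param config A [clock_config()] (only `lambda` and `s` are used).
#' @return List with `objective`, `loglik`, `penalty`
#'   (`objective = loglik - lambda * penalty`).
#' @export
pl_objective <- function(tree, ages, rates, assignment, config = clock_config()) {
  prec <- .tree_prec(tree, config$s)
  t <- numeric(prec$N)
  t[seq_along(ages)] <- ifelse(is.na(ages), 0, ages)
  t[seq_len(prec$ntip)] <- 0
  if (length(assignment) != prec$E)
    stop("assignment must have one entry per edge (", prec$E, ")")
  if (any(assignment < 1L | assignment > length(rates)))
    stop("assignment indexes outside 1..k")
  if (any(rates <= 0)) stop("rates must be > 0")
  d <- t[prec$parent] - t[prec$child]
  if (any(d < 0))
    stop("negative branch duration: ages must satisfy parent >= child")
  rr <- rates[assignment]
  mu <- rr * d * prec$s
  term <- numeric(prec$E)
  pos <- mu > 0
  term[pos] <- prec$x[pos] * log(mu[pos]) - mu[pos] - lgamma(prec$x[pos] + 1)
  bad <- !pos & prec$x > 0
  term[bad] <- -Inf
  ll <- sum(term)
  lr <- log(rr)
  pen <- sum((lr[prec$ii] - lr[prec$jj])^2)
  list(objective = ll - config$lambda * pen, loglik = ll, penalty = pen)
}

#' Fitted age of a focal clade's crown node
#'
#' @param fit A `chronogram_fit`.
#' @param focal_taxa Terminal labels of the focal clade (monophyly not
#'   required; the MRCA is used).
#' @return The crown age in My.
#' @export
crown_height <- function(fit, focal_taxa) {
  stopifnot(inherits(fit, "chronogram_fit"))
  unname(fit$ages[mrca_node(fit$tree, focal_taxa)])
}
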