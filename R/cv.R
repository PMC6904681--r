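# Terminal-deletion cross-validation for choosing the clock parameters
# (k, lambda): refit after deleting one terminal at a time and score each
# parameter combination by how much the focal clade's predicted crown height
# moves, CV = sum_i (OCH - PCH_i)^2 / OCH.

#' Terminal-deletion cross-validation score
#'
#' `CV = sum_i (och - pch_i)^2 / och`, where `och` is the focal crown height
#' on the full reference tree and `pch_i` the crown heights refitted after
#' deleting one terminal at a time. Units are My (no further normalization).
#'
#' @param och Observed crown height (My, > 0).
#' @param pchs Numeric vector of predicted crown heights (all >= 0).
#' @return Non-negative CV score; 0 iff every `pch` equals `och`.
#' @export
cv_score <- function(och, pchs) {
  if (!is.numeric(och) || length(och) != 1L || !is.finite(och) || och <= 0)
    stop("'och' must be a single positive number")
  if (length(pchs) == 0L) stop("'pchs' must be non-empty")
  if (any(!is.finite(pchs)) || any(pchs < 0))
    stop("'pchs' must be finite and >= 0")
  sum((och - pchs)^2) / och
}

#' Build the one-terminal-deletion replicate set
#'
#' One replicate per terminal of the reference tree, each carrying the pruned
#' tree and the calibrations re-resolved on it. Two degeneracies force an
#' exclusion (recorded, never silent): deleting a focal terminal when only
#' two remain (the focal crown would vanish), and deletions after which no
#' calibration bounds the root's age from above. Calibration points whose
#' clade degenerates to a single terminal with a crown role are dropped from
#' that replicate and logged.
#'
#' @param rt Reference tree (`phylo`, >= 3 terminals).
#' @param focal_taxa Terminal labels of the focal clade.
#' @param points List of [calibration_point()] objects.
#' @return List of replicates `list(label, tree, constraints,
#'   dropped_points)`, with attribute `skipped` (data.frame: label, reason).
#' @export
deletion_replicates <- function(rt, focal_taxa, points) {
  if (length(rt$tip.label) < 3L) stop("reference tree must have >= 3 terminals")
  focal_taxa <- .check_taxa(rt, focal_taxa)
  root_of <- function(tree) length(tree$tip.label) + 1L
  reps <- list(); skipped <- list()
  for (label in rt$tip.label) {
    if (label %in% focal_taxa && sum(focal_taxa != label) < 2L) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        label = label, reason = "focal crown degenerates (< 2 focal terminals)",
        stringsAsFactors = FALSE)
      next
    }
    pruned <- prune_terminal(rt, label)
    pts <- list(); dropped <- character(0)
    for (p in points) {
      taxa <- setdiff(p$taxa, label)
      if (length(taxa) == 0L ||
          (length(taxa) == 1L && p$node_role == "crown")) {
        dropped <- c(dropped, p$name)
        next
      }
      q <- p; q$taxa <- taxa
      pts[[length(pts) + 1L]] <- q
    }
    cons <- withCallingHandlers(
      resolve_calibrations(pruned, pts),
      warning = function(w) invokeRestart("muffleWarning"))
    root <- root_of(pruned)
    if (!any(cons$node == root & is.finite(cons$max_age))) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        label = label, reason = "root loses all upper age bounds",
        stringsAsFactors = FALSE)
      next
    }
    reps[[length(reps) + 1L]] <- list(label = label, tree = pruned,
                                      constraints = cons,
                                      dropped_points = dropped)
  }
  attr(reps, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(label = character(0), reason = character(0))
  reps
}

# map a fitted tree's internal-node ages onto another tree by clade leafset,
# optionally treating `drop` as deleted from the source tree's leafsets
.ages_by_leafset <- function(tree, ages, drop = NULL) {
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  out <- new.env(hash = TRUE, parent = emptyenv())
  for (v in (ntip + 1L):n) {
    labs <- setdiff(clade_terminals(tree, v), drop)
    if (length(labs) >= 2L) assign(leafset_hash(labs), ages[v], envir = out)
  }
  out
}

.map_init_ages <- function(target_tree, source_env) {
  ntip <- length(target_tree$tip.label)
  n <- ntip + target_tree$Nnode
  init <- rep(NA_real_, n)
  for (v in (ntip + 1L):n) {
    h <- leafset_hash(clade_terminals(target_tree, v))
    if (!is.null(a <- get0(h, envir = source_env))) init[v] <- a
  }
  init
}

#' Evaluate one (k, lambda) cell of the cross-validation grid
#'
#' Fits the reference tree and every deletion replicate at the given clock
#' parameters, extracts crown heights and applies [cv_score()]. Replicate
#' fits are warm-started from the reference fit's ages (matched by clade).
#'
#' @param rt Reference tree.
#' @param focal_taxa Focal clade terminals.
#' @param points Calibration points.
#' @param k,lambda Clock parameters for this cell.
#' @param config Base [clock_config()] (its `k`/`lambda` are overridden).
#' @param replicates Optional precomputed [deletion_replicates()] output.
#' @param rt_init Optional warm-start ages for the reference fit.
#' @param rt_init_rates Optional warm-start category rates for the
#'   reference fit.
#' @param rt_ladder Optional cached strict-clock ages of the reference tree
#'   (see [clock_config()]'s `ladder_ages`); replicates may carry their own
#'   cached ladder in a `ladder_ages` element.
#' @return Object of class `cv_cell`: `k`, `lambda`, `OCH`, `PCH` (named by
#'   deleted label), `CV`, `M`, `skipped`, `failed`, `converged`, plus the
#'   reference fit in `$rt_fit`.
#' @export
evaluate_cv_cell <- function(rt, focal_taxa, points, k, lambda,
                             config = clock_config(), replicates = NULL,
                             rt_init = NULL, rt_init_rates = NULL,
                             rt_ladder = NULL) {
  if (is.null(replicates))
    replicates <- deletion_replicates(rt, focal_taxa, points)
  cfg <- config; cfg$k <- as.integer(k); cfg$lambda <- lambda
  cfg$init_ages <- rt_init
  cfg$init_rates <- rt_init_rates
  cfg$ladder_ages <- rt_ladder
  cons <- withCallingHandlers(resolve_calibrations(rt, points),
                              warning = function(w) invokeRestart("muffleWarning"))
  rt_fit <- fit_chronogram(rt, cons, cfg)
  och <- crown_height(rt_fit, focal_taxa)
  pch <- numeric(0); failed <- character(0); conv <- logical(0)
  # replicate fits restart from their own cached strict-clock ladder with
  # the reference fit's category rates as one candidate seed; simply
  # warm-starting from the reference solution leaves a minority of
  # replicates in distant modes and the CV score then measures optimizer
  # noise instead of prediction stability
  for (rep in replicates) {
    cfg_rep <- cfg
    cfg_rep$init_ages <- NULL
    cfg_rep$init_rates <- rt_fit$rates
    cfg_rep$ladder_ages <- rep$ladder_ages
    cfg_rep$lean <- TRUE
    foc <- setdiff(focal_taxa, rep$label)
    fit <- tryCatch(fit_chronogram(rep$tree, rep$constraints, cfg_rep),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      failed <- c(failed, rep$label)
      next
    }
    pch <- c(pch, stats::setNames(crown_height(fit, foc), rep$label))
    conv <- c(conv, fit$converged)
  }
  structure(list(k = as.integer(k), lambda = lambda, OCH = och, PCH = pch,
                 CV = if (length(pch)) cv_score(och, pch) else NA_real_,
                 M = length(pch),
                 skipped = attr(replicates, "skipped"), failed = failed,
                 converged = rt_fit$converged, rt_fit = rt_fit),
            class = "cv_cell")
}

#' Default clock-parameter grid
#'
#' Nine rate-category counts (2 to 10 by 1) crossed with ten smoothing
#' weights (0 to 1 in exact increments of 1/9): 90 cells.
#'
#' @return List with components `k` and `lambda`.
#' @export
default_grid_axes <- function() list(k = 2:10, lambda = (0:9) / 9)

#' Exhaustive cross-validation grid search
#'
#' Evaluates every (k, lambda) cell on the reference tree and its deletion
#' replicates; the argmin cell (ties broken by smaller k, then smaller
#' lambda) selects the clock parameters.
#'
#' @inheritParams evaluate_cv_cell
#' @param k_values,lambda_values Grid axes (defaults: [default_grid_axes()]).
#' @return Object of class `cv_surface`: `table` (data.frame with one row
#'   per cell: `k`, `lambda`, `M`, `OCH`, `CV`, `n_skipped`), `argmin`
#'   (list `k`, `lambda`, `CV`), the axes, and `skipped` (deletion audit).
#' @export
cv_grid_search <- function(rt, focal_taxa, points,
                           k_values = default_grid_axes()$k,
                           lambda_values = default_grid_axes()$lambda,
                           config = clock_config()) {
  if (length(k_values) == 0L || length(lambda_values) == 0L)
    stop("grid axes must be non-empty")
  replicates <- deletion_replicates(rt, focal_taxa, points)
  # the strict-clock ladder does not depend on (k, lambda): fit it once per
  # tree and reuse it as the cold-start base across the whole grid
  cfg1 <- config; cfg1$k <- 1L
  cons_rt <- withCallingHandlers(resolve_calibrations(rt, points),
                                 warning = function(w) invokeRestart("muffleWarning"))
  rt_ladder <- tryCatch(fit_chronogram(rt, cons_rt, cfg1)$ages,
                        error = function(e) NULL)
  for (j in seq_along(replicates)) {
    lad <- tryCatch(
      fit_chronogram(replicates[[j]]$tree, replicates[[j]]$constraints,
                     cfg1)$ages,
      error = function(e) NULL)
    replicates[[j]]$ladder_ages <- lad
  }
  rows <- vector("list", length(k_values) * length(lambda_values))
  i <- 0L
  for (k in k_values) {
    rt_init_rates <- NULL
    for (lambda in lambda_values) {
      i <- i + 1L
      cell <- tryCatch(
        evaluate_cv_cell(rt, focal_taxa, points, k, lambda, config,
                         replicates = replicates,
                         rt_init_rates = rt_init_rates,
                         rt_ladder = rt_ladder),
        error = function(e) e)
      if (inherits(cell, "error")) {
        rows[[i]] <- data.frame(k = k, lambda = lambda, M = NA_integer_,
                                OCH = NA_real_, CV = NA_real_,
                                n_skipped = NA_integer_)
        next
      }
      rt_init_rates <- cell$rt_fit$rates
      rows[[i]] <- data.frame(k = cell$k, lambda = cell$lambda, M = cell$M,
                              OCH = cell$OCH, CV = cell$CV,
                              n_skipped = nrow(cell$skipped))
    }
  }
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$CV))) stop("all grid cells failed to fit")
  ok <- which(!is.na(tab$CV))
  best <- ok[order(tab$CV[ok], tab$k[ok], tab$lambda[ok])][1L]
  structure(list(table = tab,
                 argmin = list(k = tab$k[best], lambda = tab$lambda[best],
                               CV = tab$CV[best]),
                 k_values = k_values, lambda_values = lambda_values,
                 skipped = attr(replicates, "skipped")),
            class = "cv_surface")
}

#' @export
print.cv_surface <- function(x, ...) {
  cat(sprintf("cv_surface: %d cells (k in {%s}, lambda in {%s})\n",
              nrow(x$table), paste(x$k_values, collapse = ","),
              paste(format(round(x$lambda_values, 2)), collapse = ",")))
  cat(sprintf("  argmin: k* = %d, lambda* = %.2f, CV* = %.6g\n",
              x$argmin$k, x$argmin$lambda, x$argmin$CV))
  if (nrow(x$skipped))
    cat(sprintf("  %d deletion(s) skipped\n", nrow(x$skipped)))
  invisible(x)
}

#' Export a CV surface as TSV
#'
#' Columns `k, lambda, M, OCH, CV, n_skipped`, one row per grid cell;
#' lambda is printed to 2 decimals alongside its exact value.
#'
#' @param surface A `cv_surface`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_surface <- function(surface, path) {
  tab <- surface$table
  tab$lambda_label <- sprintf("%.2f", tab$lambda)
  num <- c("lambda", "OCH", "CV")
  for (cn in num) tab[[cn]] <- sprintf("%.10g", tab[[cn]])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a CV surface
#'
#' One panel per smoothing weight lambda, CV against the number of rate
#' categories k.
#'
#' @param surface A `cv_surface`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `surface`.
#' @export
plot_cv_surface <- function(surface, ...) {
  tab <- surface$table
  lv <- surface$lambda_values
  nl <- length(lv)
  nc <- ceiling(sqrt(nl)); nr <- ceiling(nl / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(3.5, 3.5, 2, 0.5),
                      mgp = c(2, 0.7, 0))
  on.exit(graphics::par(op))
  ylim <- range(tab$CV, na.rm = TRUE)
  for (l in lv) {
    d <- tab[tab$lambda == l, ]
    graphics::plot(d$k, d$CV, type = "b", pch = 19, ylim = ylim,
                   xlab = "k", ylab = "CV",
                   main = sprintf("lambda = %.2f", l), ...)
    if (surface$argmin$lambda == l)
      graphics::points(surface$argmin$k, surface$argmin$CV, col = 2, cex = 1.6)
  }
  invisible(surface)
}
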