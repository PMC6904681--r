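# Chronogram ensembles: run the (k, lambda) dating grid across collections
# of trees (optimal + bootstrap) and summarize the distribution of the focal
# clade's tMRCA.

#' Run the dating grid over collections of trees
#'
#' For every tree in every set and every (k, lambda) cell, fits a chronogram
#' and records the focal clade's crown age. Trees on which fewer than two
#' focal terminals are present, or on which no calibration bounds the root
#' from above, are skipped with a warning; individual cell failures are
#' logged, never silently dropped. The record-count identity
#' `n_records + n_failures = sum(set sizes) * grid size` is asserted on
#' return.
#'
#' @param tree_sets A named list of `multiPhylo` (or single `phylo`) objects;
#'   names label the sources (e.g. `"ML-optimal"`, `"Pars-bootstrap"`).
#' @param points Calibration points ([calibration_point()] list).
#' @param focal_taxa Terminal labels of the focal clade.
#' @param k_values,lambda_values Grid axes (defaults: [default_grid_axes()]).
#' @param config Base [clock_config()].
#' @return Object of class `tmrca_ensemble`: data.frame `records` with
#'   columns `source`, `tree_index`, `k`, `lambda`, `tmrca_My`, `converged`;
#'   plus attributes `failures` (data.frame source, tree_index, k, lambda,
#'   reason) and `planned` (the full design count).
#' @export
run_ensemble <- function(tree_sets, points, focal_taxa,
                         k_values = default_grid_axes()$k,
                         lambda_values = default_grid_axes()$lambda,
                         config = clock_config()) {
  as_set <- function(x) {
    if (inherits(x, "phylo")) structure(list(x), class = "multiPhylo") else x
  }
  if (inherits(tree_sets, "phylo") || inherits(tree_sets, "multiPhylo"))
    tree_sets <- list(trees = tree_sets)
  tree_sets <- lapply(tree_sets, as_set)
  if (is.null(names(tree_sets)) || any(!nzchar(names(tree_sets))))
    names(tree_sets) <- paste0("set", seq_along(tree_sets))
  grid <- expand.grid(lambda = lambda_values, k = k_values,
                      KEEP.OUT.ATTRS = FALSE)[, c("k", "lambda")]
  planned <- sum(vapply(tree_sets, length, integer(1))) * nrow(grid)
  recs <- vector("list", planned); fails <- list(); i <- 0L
  for (src in names(tree_sets)) {
    set <- tree_sets[[src]]
    for (ti in seq_along(set)) {
      tree <- set[[ti]]
      present <- intersect(focal_taxa, tree$tip.label)
      fail_tree <- NULL
      if (length(present) < 2L) {
        fail_tree <- "fewer than 2 focal terminals"
      } else {
        cons <- tryCatch(withCallingHandlers(
          resolve_calibrations(tree, points),
          warning = function(w) invokeRestart("muffleWarning")),
          error = function(e) e)
        if (inherits(cons, "error")) fail_tree <- conditionMessage(cons)
        else if (!any(cons$node == length(tree$tip.label) + 1L &
                      is.finite(cons$max_age)))
          fail_tree <- "root unbounded above"
      }
      if (!is.null(fail_tree)) {
        warning(sprintf("%s tree %d skipped: %s", src, ti, fail_tree))
        fails[[length(fails) + 1L]] <- data.frame(
          source = src, tree_index = ti, k = NA_integer_, lambda = NA_real_,
          reason = fail_tree, stringsAsFactors = FALSE)
        next
      }
      init <- NULL; init_rates <- NULL
      for (g in seq_len(nrow(grid))) {
        cfg <- config
        cfg$k <- as.integer(grid$k[g]); cfg$lambda <- grid$lambda[g]
        cfg$init_ages <- init
        if (!is.null(init_rates) && length(init_rates) == cfg$k)
          cfg$init_rates <- init_rates
        fit <- tryCatch(fit_chronogram(tree, cons, cfg),
                        error = function(e) e)
        if (inherits(fit, "error")) {
          fails[[length(fails) + 1L]] <- data.frame(
            source = src, tree_index = ti, k = grid$k[g],
            lambda = grid$lambda[g], reason = conditionMessage(fit),
            stringsAsFactors = FALSE)
          next
        }
        init <- fit$ages
        init_rates <- fit$rates
        i <- i + 1L
        recs[[i]] <- data.frame(
          source = src, tree_index = ti, k = grid$k[g],
          lambda = grid$lambda[g],
          tmrca_My = crown_height(fit, present), converged = fit$converged,
          stringsAsFactors = FALSE)
      }
    }
  }
  records <- if (i) do.call(rbind, recs[seq_len(i)]) else
    data.frame(source = character(0), tree_index = integer(0),
               k = integer(0), lambda = numeric(0), tmrca_My = numeric(0),
               converged = logical(0))
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(source = character(0), tree_index = integer(0),
               k = integer(0), lambda = numeric(0), reason = character(0))
  n_failed_cells <- sum(!is.na(failures$k))
  n_failed_trees <- sum(is.na(failures$k))
  stopifnot(nrow(records) + n_failed_cells + n_failed_trees * nrow(grid) ==
              planned)
  structure(list(records = records,
                 grid = grid,
                 focal_taxa = focal_taxa),
            failures = failures, planned = planned,
            class = "tmrca_ensemble")
}

#' @export
print.tmrca_ensemble <- function(x, ...) {
  f <- attr(x, "failures")
  cat(sprintf("tmrca_ensemble: %d records (%d planned, %d failures logged)\n",
              nrow(x$records), attr(x, "planned"), nrow(f)))
  cat(sprintf("  sources: %s\n",
              paste(unique(x$records$source), collapse = ", ")))
  invisible(x)
}

#' Summarize a tMRCA ensemble
#'
#' Quantiles use linear interpolation between order statistics (type 7,
#' [stats::quantile()]'s default); the central 75% interval is the 12.5th to
#' 87.5th percentile range; the below-threshold fraction uses strict
#' inequality. Non-converged fits are included unless `converged_only`.
#'
#' @param ensemble A `tmrca_ensemble` (or a numeric vector of tMRCAs).
#' @param threshold Age threshold in My for the below-threshold count.
#' @param converged_only Drop records from non-converged fits first.
#' @param bins Number of histogram bins (equal width on log10(My) when all
#'   values are positive, linear otherwise).
#' @return Object of class `tmrca_summary`: `n`, `min`, `q1`, `q3`, `max`,
#'   `central75` (length-2), `threshold`, `n_below`, `frac_below`,
#'   `hist_breaks`, `hist_counts`, `log10_bins`.
#' @export
summarize_tmrca <- function(ensemble, threshold = 1, converged_only = FALSE,
                            bins = 50L) {
  if (inherits(ensemble, "tmrca_ensemble")) {
    rec <- ensemble$records
    if (converged_only) rec <- rec[rec$converged, , drop = FALSE]
    v <- rec$tmrca_My
  } else v <- as.numeric(ensemble)
  if (length(v) == 0L) stop("no tMRCA records to summarize")
  q <- stats::quantile(v, c(0.125, 0.25, 0.75, 0.875), type = 7, names = FALSE)
  log10_bins <- all(v > 0) && length(unique(v)) > 1L
  if (log10_bins) {
    lb <- seq(log10(min(v)), log10(max(v)), length.out = bins + 1L)
    lb[1L] <- lb[1L] - 1e-9; lb[bins + 1L] <- lb[bins + 1L] + 1e-9
    counts <- graphics::hist(log10(v), breaks = lb, plot = FALSE)$counts
    breaks <- 10^lb
  } else {
    h <- graphics::hist(v, breaks = bins, plot = FALSE)
    counts <- h$counts; breaks <- h$breaks
  }
  stopifnot(sum(counts) == length(v))
  structure(list(n = length(v), min = min(v), q1 = q[2L], q3 = q[3L],
                 max = max(v), central75 = c(q[1L], q[4L]),
                 threshold = threshold, n_below = sum(v < threshold),
                 frac_below = mean(v < threshold),
                 hist_breaks = breaks, hist_counts = counts,
                 log10_bins = log10_bins),
            class = "tmrca_summary")
}

#' @export
print.tmrca_summary <- function(x, ...) {
  cat(sprintf("tmrca_summary over %d chronograms:\n", x$n))
  cat(sprintf("  range %.4g - %.4g My; Q1 = %.4g, Q3 = %.4g\n",
              x$min, x$max, x$q1, x$q3))
  cat(sprintf("  central 75%%: %.4g - %.4g My\n",
              x$central75[1L], x$central75[2L]))
  cat(sprintf("  %d (%.1f%%) below %g My\n",
              x$n_below, 100 * x$frac_below, x$threshold))
  invisible(x)
}

#' Plot the tMRCA histogram of an ensemble
#'
#' @param summary A `tmrca_summary`.
#' @param main Plot title.
#' @return Invisibly, `summary`.
#' @export
plot_tmrca_hist <- function(summary, main = "tMRCA distribution") {
  mids <- (utils::head(summary$hist_breaks, -1) +
             utils::tail(summary$hist_breaks, -1)) / 2
  if (summary$log10_bins) {
    graphics::plot(log10(mids), summary$hist_counts, type = "h", lwd = 3,
                   xlab = "log10(tMRCA, My)", ylab = "chronograms",
                   main = main)
    graphics::abline(v = log10(summary$threshold), lty = 2, col = 2)
  } else {
    graphics::plot(mids, summary$hist_counts, type = "h", lwd = 3,
                   xlab = "tMRCA (My)", ylab = "chronograms", main = main)
    graphics::abline(v = summary$threshold, lty = 2, col = 2)
  }
  invisible(summary)
}

#' Export ensemble records, summary and histogram
#'
#' TSV outputs are formatted deterministically, so repeated seeded runs are
#' byte-identical.
#'
#' @param ensemble A `tmrca_ensemble`.
#' @param summary A `tmrca_summary` (default: computed with `threshold = 1`).
#' @param dir Output directory (created if needed).
#' @param basename File stem for the three outputs.
#' @return Named character vector of the written paths, invisibly.
#' @export
export_ensemble <- function(ensemble, summary = NULL, dir = ".",
                            basename = "ensemble") {
  if (is.null(summary)) summary <- summarize_tmrca(ensemble)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rec_path <- file.path(dir, paste0(basename, "_records.tsv"))
  sum_path <- file.path(dir, paste0(basename, "_summary.tsv"))
  fig_path <- file.path(dir, paste0(basename, "_hist.png"))
  rec <- ensemble$records
  rec$lambda <- sprintf("%.10g", rec$lambda)
  rec$tmrca_My <- sprintf("%.10g", rec$tmrca_My)
  utils::write.table(rec, rec_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  s <- data.frame(n = summary$n, min = summary$min, q1 = summary$q1,
                  q3 = summary$q3, max = summary$max,
                  central75_lo = summary$central75[1L],
                  central75_hi = summary$central75[2L],
                  threshold = summary$threshold, n_below = summary$n_below,
                  frac_below = summary$frac_below)
  for (cn in names(s)) if (is.numeric(s[[cn]])) s[[cn]] <- sprintf("%.10g", s[[cn]])
  utils::write.table(s, sum_path, sep = "\t", quote = FALSE, row.names = FALSE)
  grDevices::png(fig_path, width = 800, height = 500)
  plot_tmrca_hist(summary)
  grDevices::dev.off()
  invisible(c(records = rec_path, summary = sum_path, figure = fig_path))
}
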