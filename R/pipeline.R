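# File-level pipeline commands: each reads plain-text inputs (Newick,
# calibration TSV, taxa list), runs one analysis stage, and writes outputs
# plus a JSON manifest recording inputs, seed and checksums, so seeded runs
# are auditable and byte-reproducible.

.file_hash <- function(path) {
  sprintf("%08x", .hash31(paste(readLines(path, warn = FALSE), collapse = "\n")))
}

.write_manifest <- function(path, fields, outputs) {
  fields$outputs <- lapply(outputs, function(f)
    list(path = unname(f), hash = .file_hash(f)))
  fields$package <- as.character(utils::packageVersion("chronocv"))
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a plain-text key=value run configuration
#'
#' Lines of the form `key = value`; `#` starts a comment. Values are
#' returned as character and coerced by the consuming command. CLI flags
#' take precedence over config-file values, which take precedence over
#' built-in defaults.
#'
#' @param path Path to the config file.
#' @return Named list of character values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(p) trimws(paste(p[-1], collapse = "="))),
                  vapply(kv, function(p) trimws(p[1]), character(1)))
}

#' Simulate a benchmark to disk
#'
#' @param profile Benchmark profile name (see [make_benchmark()]).
#' @param seed Top-level seed.
#' @param outdir Output directory.
#' @param n_bootstrap,nni_prob Passed to [make_benchmark()].
#' @return The `synth_truth`, invisibly.
#' @export
pipeline_simulate <- function(profile, seed, outdir, n_bootstrap = 100L,
                              nni_prob = 0.1) {
  truth <- make_benchmark(profile, seed = seed, dir = outdir,
                          n_bootstrap = n_bootstrap, nni_prob = nni_prob)
  .write_manifest(file.path(outdir, "manifest.json"),
                  list(command = "simulate", profile = profile, seed = seed,
                       n_bootstrap = n_bootstrap, nni_prob = nni_prob),
                  truth$files)
  invisible(truth)
}

#' Date one phylogram and write the chronogram
#'
#' Writes `chronogram.nwk`, `branch_rates.tsv` (per-branch duration, rate
#' and category) and `manifest.json` into `outdir`.
#'
#' @param tree_file Newick phylogram path.
#' @param calibration_file Calibration TSV path.
#' @param outdir Output directory.
#' @param k,lambda,s Clock parameters (see [clock_config()]).
#' @param seed Seed for restarts.
#' @param n_starts Restarts for the fit.
#' @return The `chronogram_fit`, invisibly.
#' @export
pipeline_date <- function(tree_file, calibration_file, outdir, k = 2,
                          lambda = 0, s = 3754, seed = 1, n_starts = 1L) {
  tree <- read_tree_file(tree_file)[[1L]]
  points <- read_calibrations(calibration_file)
  cons <- resolve_calibrations(tree, points)
  cfg <- clock_config(k = k, lambda = lambda, s = s,
                      seed = .substream(seed, "date"), n_starts = n_starts)
  fit <- fit_chronogram(tree, cons, cfg)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  chron_path <- file.path(outdir, "chronogram.nwk")
  rates_path <- file.path(outdir, "branch_rates.tsv")
  writeLines(write_newick(fit$tree), chron_path)
  tab <- data.frame(edge = seq_len(nrow(fit$tree$edge)),
                    parent = fit$tree$edge[, 1L],
                    child = fit$tree$edge[, 2L],
                    duration_My = sprintf("%.10g", fit$tree$edge.length),
                    rate = sprintf("%.10g", fit$edge_rate),
                    category = fit$edge_category)
  utils::write.table(tab, rates_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  .write_manifest(file.path(outdir, "manifest.json"),
                  list(command = "date", tree_file = tree_file,
                       tree_hash = .file_hash(tree_file),
                       calibration_file = calibration_file,
                       calibration_hash = .file_hash(calibration_file),
                       k = k, lambda = lambda, s = s, seed = seed,
                       objective = fit$objective, loglik = fit$loglik,
                       penalty = fit$penalty, converged = fit$converged),
                  c(chron_path, rates_path))
  invisible(fit)
}

#' Run the cross-validation grid on one reference tree
#'
#' Writes `cv_surface.tsv`, `cv_surface.png` and `manifest.json` (including
#' the argmin cell) into `outdir`.
#'
#' @param tree_file Newick phylogram path (the reference tree).
#' @param calibration_file Calibration TSV path.
#' @param focal_file Plain-text file with one focal terminal label per line.
#' @param outdir Output directory.
#' @param k_values,lambda_values Grid axes (defaults: [default_grid_axes()]).
#' @param s Alignment length.
#' @param seed Seed.
#' @return The `cv_surface`, invisibly.
#' @export
pipeline_cv_grid <- function(tree_file, calibration_file, focal_file, outdir,
                             k_values = default_grid_axes()$k,
                             lambda_values = default_grid_axes()$lambda,
                             s = 3754, seed = 1) {
  tree <- read_tree_file(tree_file)[[1L]]
  points <- read_calibrations(calibration_file)
  focal <- readLines(focal_file, warn = FALSE)
  focal <- focal[nzchar(trimws(focal))]
  cfg <- clock_config(s = s, seed = .substream(seed, "cv"))
  surf <- cv_grid_search(tree, focal, points, k_values, lambda_values, cfg)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  tsv <- file.path(outdir, "cv_surface.tsv")
  fig <- file.path(outdir, "cv_surface.png")
  write_cv_surface(surf, tsv)
  grDevices::png(fig, width = 1000, height = 800)
  plot_cv_surface(surf)
  grDevices::dev.off()
  .write_manifest(file.path(outdir, "manifest.json"),
                  list(command = "cv-grid", tree_file = tree_file,
                       tree_hash = .file_hash(tree_file),
                       calibration_file = calibration_file, s = s, seed = seed,
                       k_star = surf$argmin$k, lambda_star = surf$argmin$lambda,
                       cv_star = surf$argmin$CV,
                       n_cells = nrow(surf$table)),
                  tsv)
  invisible(surf)
}

#' Run the chronogram ensemble over tree files
#'
#' Each input file is one tree set (its basename, or the vector's names,
#' labels the source). Writes records/summary TSVs, the tMRCA histogram and
#' a manifest; prints the record-count identity.
#'
#' @param tree_files Character vector of multi-tree Newick paths (optionally
#'   named with source labels).
#' @param calibration_file Calibration TSV path.
#' @param focal_file Focal taxa list path.
#' @param outdir Output directory.
#' @param k_values,lambda_values Grid axes.
#' @param s Alignment length.
#' @param threshold Below-threshold age (My) for the summary.
#' @param seed Seed.
#' @param converged_only Summarize converged fits only.
#' @return List with the `tmrca_ensemble` and `tmrca_summary`, invisibly.
#' @export
pipeline_ensemble <- function(tree_files, calibration_file, focal_file,
                              outdir, k_values = default_grid_axes()$k,
                              lambda_values = default_grid_axes()$lambda,
                              s = 3754, threshold = 1, seed = 1,
                              converged_only = FALSE) {
  labels <- names(tree_files)
  if (is.null(labels)) labels <- basename(tree_files)
  sets <- stats::setNames(lapply(tree_files, read_tree_file), labels)
  points <- read_calibrations(calibration_file)
  focal <- readLines(focal_file, warn = FALSE)
  focal <- focal[nzchar(trimws(focal))]
  cfg <- clock_config(s = s, seed = .substream(seed, "ensemble"))
  ens <- run_ensemble(sets, points, focal, k_values, lambda_values, cfg)
  summ <- summarize_tmrca(ens, threshold = threshold,
                          converged_only = converged_only)
  paths <- export_ensemble(ens, summ, dir = outdir)
  message(sprintf(
    "record-count identity: %d records + %d logged failures = %d planned",
    nrow(ens$records), attr(ens, "planned") - nrow(ens$records),
    attr(ens, "planned")))
  .write_manifest(file.path(outdir, "manifest.json"),
                  list(command = "ensemble",
                       tree_files = as.list(unname(tree_files)),
                       calibration_file = calibration_file, s = s,
                       threshold = threshold, seed = seed,
                       converged_only = converged_only,
                       n_records = nrow(ens$records),
                       n_planned = attr(ens, "planned"),
                       n_failures = nrow(attr(ens, "failures"))),
                  c(paths[["records"]], paths[["summary"]]))
  invisible(list(ensemble = ens, summary = summ))
}
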