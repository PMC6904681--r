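# Calibration tables: clade-anchored [min, max] age bounds (fossil,
# geological or secondary evidence) and their resolution onto concrete nodes
# of a given tree.

#' Construct a calibration point
#'
#' A calibration point binds a clade (defined by its terminal labels) to an
#' age box. `node_role = "crown"` constrains the clade's MRCA;
#' `node_role = "stem"` constrains the node where the clade's subtending
#' branch attaches (the MRCA's parent), the convention used by fossil
#' calibrations.
#'
#' @param name Human-readable point name.
#' @param node_role `"crown"` or `"stem"`.
#' @param taxa Character vector of terminal labels defining the clade.
#' @param min_age,max_age Age bounds in My; `NA` for an open side (at least
#'   one side must be given; if both, `min_age < max_age`).
#' @param evidence Free-text evidence class (`fossil`, `geological`,
#'   `secondary`).
#' @return An object of class `calibration_point`.
#' @export
calibration_point <- function(name, node_role, taxa, min_age = NA_real_,
                              max_age = NA_real_, evidence = NA_character_) {
  node_role <- as.character(node_role)
  if (!node_role %in% c("crown", "stem"))
    stop("unknown node_role '", node_role, "' for calibration '", name,
         "' (must be 'crown' or 'stem')")
  taxa <- unique(as.character(taxa))
  if (length(taxa) == 0L || any(!nzchar(taxa)))
    stop("calibration '", name, "': clade taxa must be non-empty")
  min_age <- as.numeric(min_age); max_age <- as.numeric(max_age)
  if (is.na(min_age) && is.na(max_age))
    stop("calibration '", name, "': at least one of min_age/max_age required")
  if (!is.na(min_age) && min_age < 0)
    stop("calibration '", name, "': min_age must be >= 0")
  if (!is.na(min_age) && !is.na(max_age) && min_age >= max_age)
    stop("calibration '", name, "': min_age (", min_age,
         ") must be smaller than max_age (", max_age, ")")
  structure(list(name = name, node_role = node_role, taxa = taxa,
                 min_age = min_age, max_age = max_age, evidence = evidence),
            class = "calibration_point")
}

#' @export
print.calibration_point <- function(x, ...) {
  cat(sprintf("calibration '%s' [%s]: [%s, %s] My on %d taxa (%s)\n",
              x$name, x$node_role,
              ifelse(is.na(x$min_age), "-", format(x$min_age)),
              ifelse(is.na(x$max_age), "-", format(x$max_age)),
              length(x$taxa), x$evidence))
  invisible(x)
}

#' Load a calibration table from TSV
#'
#' Expected columns: `name`, `node_role`, `min_age`, `max_age`, `evidence`,
#' `taxa` (semicolon-separated terminal labels). Published calibration tables
#' often state one-sided bounds on separate rows (a fossil minimum and a
#' secondary maximum for the same node); rows sharing the same `name` are
#' merged into a single point carrying both bounds, taking the largest stated
#' minimum and the smallest stated maximum.
#'
#' @param path Path to the TSV file.
#' @return A list of [calibration_point()] objects (empty, with a warning,
#'   for a table with no rows).
#' @export
read_calibrations <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  need <- c("name", "node_role", "min_age", "max_age", "evidence", "taxa")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("calibration table lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(tab) == 0L) {
    warning("empty calibration table: ", path)
    return(list())
  }
  tab$min_age <- suppressWarnings(as.numeric(tab$min_age))
  tab$max_age <- suppressWarnings(as.numeric(tab$max_age))
  pts <- lapply(split(tab, factor(tab$name, levels = unique(tab$name))),
                function(rows) {
    mins <- rows$min_age[!is.na(rows$min_age)]
    maxs <- rows$max_age[!is.na(rows$max_age)]
    roles <- unique(rows$node_role)
    if (length(roles) != 1L)
      stop("calibration '", rows$name[1], "': conflicting node_role across rows")
    taxa <- unique(unlist(strsplit(rows$taxa, ";", fixed = TRUE)))
    taxa <- trimws(taxa)
    ev <- paste(unique(rows$evidence[!is.na(rows$evidence)]), collapse = ";")
    calibration_point(
      name = rows$name[1], node_role = roles, taxa = taxa,
      min_age = if (length(mins)) max(mins) else NA_real_,
      max_age = if (length(maxs)) min(maxs) else NA_real_,
      evidence = if (nzchar(ev)) ev else NA_character_)
  })
  names(pts) <- NULL
  pts
}

#' Write calibration points as TSV
#'
#' Inverse of [read_calibrations()] (one merged row per point).
#'
#' @param points List of [calibration_point()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibrations <- function(points, path) {
  rows <- do.call(rbind, lapply(points, function(p)
    data.frame(name = p$name, node_role = p$node_role,
               min_age = p$min_age, max_age = p$max_age,
               evidence = p$evidence,
               taxa = paste(p$taxa, collapse = ";"),
               stringsAsFactors = FALSE)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Resolve calibration points onto nodes of a tree
#'
#' Crown points map to `mrca_node(tree, taxa)`; stem points map to that
#' node's parent. Points whose clade is not monophyletic in this particular
#' tree are skipped with a warning (bootstrap and parsimony trees routinely
#' fail to recover a calibrated clade); unknown taxa are an error. Several
#' points landing on the same node are intersected into one box; an empty
#' intersection is an error naming the offending points.
#'
#' @param tree A rooted `phylo`.
#' @param points List of [calibration_point()] objects.
#' @return A data.frame with columns `node`, `min_age`, `max_age`, `name`
#'   (provenance), one row per constrained node, with attribute `skipped`
#'   (data.frame of point name + reason) recording unresolvable points.
#'   Open sides are encoded as `min_age = 0` / `max_age = Inf`.
#' @export
resolve_calibrations <- function(tree, points) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  rows <- list(); skipped <- list()
  for (p in points) {
    .check_taxa(tree, p$taxa)   # unknown taxa are fatal
    if (!is_clade(tree, p$taxa)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(name = p$name, reason = "clade not monophyletic in this tree",
                   stringsAsFactors = FALSE)
      warning("calibration '", p$name, "' skipped: clade not monophyletic")
      next
    }
    node <- mrca_node(tree, p$taxa)
    if (p$node_role == "stem") {
      if (node == root) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(name = p$name, reason = "stem of a clade spanning the root",
                     stringsAsFactors = FALSE)
        warning("calibration '", p$name, "' skipped: clade spans the root, ",
                "no stem node exists")
        next
      }
      node <- tree$edge[tree$edge[, 2L] == node, 1L]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      node = node,
      min_age = if (is.na(p$min_age)) 0 else p$min_age,
      max_age = if (is.na(p$max_age)) Inf else p$max_age,
      name = p$name, stringsAsFactors = FALSE)
  }
  if (length(rows)) {
    res <- do.call(rbind, rows)
    # intersect boxes landing on the same node
    res <- do.call(rbind, lapply(split(res, res$node), function(d) {
      out <- data.frame(node = d$node[1], min_age = max(d$min_age),
                        max_age = min(d$max_age),
                        name = paste(d$name, collapse = " & "),
                        stringsAsFactors = FALSE)
      if (out$min_age > out$max_age)
        stop("incompatible calibrations on one node: ", out$name,
             " (min ", out$min_age, " > max ", out$max_age, ")")
      out
    }))
    rownames(res) <- NULL
  } else {
    res <- data.frame(node = integer(0), min_age = numeric(0),
                      max_age = numeric(0), name = character(0),
                      stringsAsFactors = FALSE)
  }
  attr(res, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(name = character(0), reason = character(0))
  res
}
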