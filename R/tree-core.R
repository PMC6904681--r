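# Rooted-tree plumbing on top of ape's "phylo" container: validated Newick
# I/O, MRCA queries, terminal pruning and node ages for ultrametric trees.

#' Read a single rooted Newick tree
#'
#' Parses one Newick statement into an [ape::read.tree()] `phylo` object with
#' extra validation: balanced parentheses, a terminating semicolon, unique
#' non-empty terminal labels. Square-bracket comments are stripped before
#' parsing. Branch lengths absent from the input default to 0 with a warning,
#' so phylograms exported without lengths on some edges remain usable.
#'
#' @param text A character scalar holding exactly one Newick statement.
#' @return A rooted `phylo` object.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
#' @export
read_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    stop("'text' must be a single character string")
  txt <- gsub("\\[[^]]*\\]", "", text)      # drop [comments]
  txt <- trimws(txt)
  if (!nzchar(txt)) stop("Newick parse error: empty input")
  # parenthesis balance with offending position
  chars <- strsplit(txt, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("Newick parse error: unmatched ')' at position %d", i))
    }
  }
  if (depth > 0L)
    stop(sprintf("Newick parse error: %d unclosed '(' at end of input", depth))
  if (!grepl(";\\s*$", txt))
    stop(sprintf("Newick parse error: statement not terminated by ';' (position %d)",
                 nchar(txt)))
  if (sum(chars == ";") > 1L)
    stop("Newick parse error: more than one statement; use read_tree_list()")
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error: unreadable statement")
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  if (anyDuplicated(tr$tip.label))
    stop("duplicate terminal labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (any(!nzchar(tr$tip.label))) stop("empty terminal label in Newick input")
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    warning("missing branch lengths defaulted to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0))
    stop("negative branch length in input tree")
  if (any(!is.finite(tr$edge.length)))
    stop("non-finite branch length in input tree")
  tr
}

#' Write a tree as a Newick string
#'
#' @param tree A `phylo` object.
#' @param digits Significant digits for branch lengths.
#' @return A character scalar ending in `";"`.
#' @export
write_newick <- function(tree, digits = 12) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = digits)
}

#' Read an ordered set of Newick trees
#'
#' One Newick statement per line/record; any malformed record aborts with its
#' (1-based) index. The result is a `multiPhylo` carrying a `source` attribute
#' naming the collection (e.g. `"ML-bootstrap"`).
#'
#' @param text Character scalar (possibly multi-line) or character vector of
#'   Newick records.
#' @param source Label for the collection.
#' @return A `multiPhylo` preserving input order.
#' @export
read_tree_list <- function(text, source = "trees") {
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  text <- text[nzchar(trimws(text))]
  if (length(text) == 0L) stop("empty tree set")
  trees <- vector("list", length(text))
  for (i in seq_along(text)) {
    trees[[i]] <- tryCatch(read_newick(text[i]),
                           error = function(e)
                             stop(sprintf("record %d: %s", i, conditionMessage(e))))
  }
  class(trees) <- "multiPhylo"
  attr(trees, "source") <- source
  trees
}

#' @rdname read_tree_list
#' @param path Path to a multi-tree Newick file.
#' @export
read_tree_file <- function(path, source = basename(path)) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  read_tree_list(readLines(path, warn = FALSE), source = source)
}

.check_taxa <- function(tree, taxa) {
  taxa <- unique(as.character(taxa))
  if (length(taxa) == 0L) stop("'taxa' must be non-empty")
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("unknown terminal label(s): ", paste(missing, collapse = ", "))
  taxa
}

#' Most recent common ancestor of a set of terminals
#'
#' @param tree A rooted `phylo`.
#' @param taxa Character vector of terminal labels (all present in `tree`).
#' @return The node id (ape numbering) of the MRCA; for a single terminal,
#'   the terminal's own id.
#' @export
mrca_node <- function(tree, taxa) {
  taxa <- .check_taxa(tree, taxa)
  if (length(taxa) == 1L) return(match(taxa, tree$tip.label))
  ape::getMRCA(tree, taxa)
}

#' Test whether a terminal set forms a clade
#'
#' TRUE iff the terminals descending from `mrca_node(tree, taxa)` are exactly
#' `taxa`.
#'
#' @inheritParams mrca_node
#' @return Logical scalar.
#' @export
is_clade <- function(tree, taxa) {
  taxa <- .check_taxa(tree, taxa)
  if (length(taxa) == 1L) return(TRUE)
  setequal(clade_terminals(tree, mrca_node(tree, taxa)), taxa)
}

#' Terminal labels descending from a node
#'
#' @param tree A rooted `phylo`.
#' @param node Node id (tip or internal).
#' @return Character vector of terminal labels.
#' @export
clade_terminals <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  tree$tip.label[.tips_under(tree, node)]
}

# tip indices under an internal node (iterative stack; no recursion limits)
.tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v <= ntip) out <- c(out, v)
    else stack <- c(stack, kids[[as.character(v)]])
  }
  sort(out)
}

#' Remove one terminal from a tree
#'
#' The terminal and its branch are removed; the resulting degree-2 node is
#' suppressed with its two incident branch lengths summed, so all pairwise
#' path lengths among the remaining terminals are unchanged. The input tree
#' is not modified.
#'
#' @param tree A rooted `phylo` with at least 3 terminals.
#' @param label Terminal label to remove.
#' @return A new `phylo` with one fewer terminal.
#' @export
prune_terminal <- function(tree, label) {
  label <- .check_taxa(tree, label)
  if (length(label) != 1L) stop("prune one terminal at a time")
  if (length(tree$tip.label) < 3L)
    stop("cannot prune: tree would be left with fewer than 2 terminals")
  ape::drop.tip(tree, label)
}

#' Node ages of an ultrametric chronogram
#'
#' Ages are distances to the (contemporaneous) tips: every tip has age 0 and
#' a parent is at least as old as its children. The tree must be ultrametric
#' within a relative tolerance of the root age; otherwise an error reports
#' the worst tip-depth spread.
#'
#' @param tree A `phylo` whose branch lengths are time durations.
#' @param tol Relative tolerance on the tip-depth spread (fraction of root age).
#' @return Numeric vector of ages indexed by node id (tips first, then
#'   internal nodes, ape numbering).
#' @export
node_ages <- function(tree, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  tipd <- depth[seq_len(ntip)]
  root_age <- max(tipd)
  spread <- max(tipd) - min(tipd)
  if (root_age > 0 && spread > tol * root_age)
    stop(sprintf(
      "tree is not ultrametric: tip-depth spread %.6g exceeds %.2g of root age %.6g",
      spread, tol, root_age))
  ages <- root_age - depth
  ages[seq_len(ntip)] <- 0
  ages[ages < 0] <- 0
  ages
}

#' Tabulate node ages with clade fingerprints
#'
#' One row per node with a deterministic hash of the node's sorted terminal
#' set, so ages of matching clades can be joined across trees that do not
#' share node numbering.
#'
#' @param tree An ultrametric `phylo` (ages in My).
#' @param tol Passed to [node_ages()].
#' @return A data.frame with columns `node_id`, `clade_leafset_hash`, `age_My`.
#' @export
node_age_table <- function(tree, tol = 1e-6) {
  ages <- node_ages(tree, tol = tol)
  n <- length(ages)
  hashes <- vapply(seq_len(n), function(v)
    leafset_hash(clade_terminals(tree, v)), character(1))
  data.frame(node_id = seq_len(n), clade_leafset_hash = hashes,
             age_My = ages, stringsAsFactors = FALSE)
}

#' Deterministic fingerprint of a terminal set
#'
#' Order-invariant polynomial hash of the sorted labels; used to match clades
#' across trees and to checksum outputs.
#'
#' @param labels Character vector of terminal labels.
#' @return Hex string of a 31-bit hash.
#' @export
leafset_hash <- function(labels) {
  s <- paste(sort(as.character(labels)), collapse = "|")
  sprintf("%08x", .hash31(s))
}

# polynomial string hash mod (2^31 - 1), exact in double arithmetic
.hash31 <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  h
}

#' Export a node-age table as TSV
#'
#' @param tree An ultrametric `phylo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_node_ages <- function(tree, path) {
  tab <- node_age_table(tree)
  tab$age_My <- sprintf("%.10g", tab$age_My)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
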