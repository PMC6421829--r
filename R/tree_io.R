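#' Read a rooted phylogenetic tree with branch lengths
#'
#' Thin, validating wrapper around [ape::read.tree()]. The tree must carry a
#' branch length on every edge (Faith's PD and UniFrac are undefined without
#' them); zero-length branches are accepted and contribute nothing. A
#' bifurcating or basal-polytomy root is accepted as-is: the basal node is
#' treated as the root for all root-inclusive computations. Internal node
#' labels and any root edge are ignored.
#'
#' @param path Newick file.
#' @return an [ape::phylo] tree.
#' @export
read_tree <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) abort("'%s': unreadable Newick (%s)", path,
                                           conditionMessage(e)))
  if (is.null(tr)) abort("'%s': unreadable Newick", path)
  validate_tree(tr, path)
}

validate_tree <- function(tr, what = "tree") {
  if (!inherits(tr, "phylo")) abort("%s: not a phylogenetic tree", what)
  if (is.null(tr$edge.length))
    abort("%s: no branch lengths; PD and UniFrac are undefined", what)
  if (length(tr$edge.length) != nrow(tr$edge) || anyNA(tr$edge.length))
    abort("%s: missing branch length on %d edge(s)", what,
          sum(is.na(tr$edge.length)) + abs(nrow(tr$edge) - length(tr$edge.length)))
  if (any(tr$edge.length < 0)) abort("%s: negative branch length", what)
  if (anyDuplicated(tr$tip.label)) abort("%s: duplicate tip labels", what)
  if (!sum(tr$edge.length) > 0) abort("%s: total branch length must be positive", what)
  tr
}

#' Write a tree to Newick
#' @param tree an [ape::phylo] tree.
#' @param path output file.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

# Check every zOTU with counts maps to exactly one tip; returns the tree
# pruned to the table's zOTU set.
prune_to_table <- function(tree, otu_ids) {
  missing <- setdiff(otu_ids, tree$tip.label)
  if (length(missing))
    abort("zOTU(s) absent from tree: %s%s",
          paste(utils::head(missing, 5), collapse = ", "),
          if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5) else "")
  extra <- setdiff(tree$tip.label, otu_ids)
  if (length(extra)) tree <- ape::drop.tip(tree, extra)
  tree
}
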