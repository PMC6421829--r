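#' Bray-Curtis dissimilarity between two samples
#'
#' The abundance-weighted form is `sum(|x - y|) / sum(x + y)`; the unweighted
#' (binary, Sorensen) form is `(A + B - 2J) / (A + B)` with `A`, `B` the
#' species counts of each sample and `J` the number of shared species.
#' Abundance information is deliberately discarded in the unweighted form so
#' that rare community members weigh as much as dominant ones.
#'
#' @param x,y non-negative numeric vectors of equal length (counts or
#'   relative abundances over the same taxon set).
#' @param weighted use abundances (`TRUE`, default) or presence/absence.
#' @return dissimilarity in `[0, 1]`.
#' @examples
#' bray_curtis(c(1, 0, 3), c(2, 1, 0))            # 5/7
#' bray_curtis(c(1, 0, 3), c(2, 1, 0), weighted = FALSE)  # 0.5
#' @export
bray_curtis <- function(x, y, weighted = TRUE) {
  if (length(x) != length(y)) abort("bray_curtis: length mismatch")
  if (any(x < 0) || any(y < 0)) abort("bray_curtis: negative abundances")
  if (sum(x) == 0 && sum(y) == 0)
    abort("bray_curtis: both samples empty; dissimilarity undefined")
  if (weighted) {
    sum(abs(x - y)) / sum(x + y)
  } else {
    a <- sum(x > 0); b <- sum(y > 0); j <- sum(x > 0 & y > 0)
    (a + b - 2 * j) / (a + b)
  }
}

# Per-branch bookkeeping for UniFrac and Faith's PD: for a tree pruned to the
# zOTU set, M is the (tips x edges) 0/1 incidence of "tip descends from this
# edge" and `lengths` the matching branch lengths. Any root edge (tr$root.edge)
# is outside tr$edge and therefore never contributes.
branch_table <- function(tree, otu_ids) {
  tree <- prune_to_table(tree, otu_ids)
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  desc <- matrix(0, ntip + nnode, ntip)
  desc[cbind(seq_len(ntip), seq_len(ntip))] <- 1
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    desc[p, ] <- desc[p, ] + desc[ch, ]
  }
  M <- t(desc[tree$edge[, 2L], , drop = FALSE])  # tips x edges
  rownames(M) <- tree$tip.label
  list(M = M, lengths = tree$edge.length, tree = tree)
}

#' UniFrac dissimilarity between two samples
#'
#' Computed branch-wise from the fraction of each sample's reads descending
#' from every branch (`p_b`, `q_b`). Unweighted:
#' `sum(l_b * |[p_b>0] - [q_b>0]|) / sum(l_b * [p_b>0 or q_b>0])`.
#' Weighted (normalised, the GUniFrac `d_1` form):
#' `sum(l_b * |p_b - q_b|) / sum(l_b * (p_b + q_b))`. Both depend only on
#' within-sample proportions, so rescaling one sample's counts changes
#' nothing. Rarefaction, where wanted, is the caller's job.
#'
#' @param x,y non-negative count/abundance vectors named by (or ordered as)
#'   the tree's tips.
#' @param tree rooted [ape::phylo] tree with branch lengths covering all
#'   taxa present in `x` or `y`.
#' @param weighted abundance-weighted (`TRUE`) or presence/absence.
#' @return dissimilarity in `[0, 1]`.
#' @export
unifrac <- function(x, y, tree, weighted = TRUE) {
  if (length(x) != length(y)) abort("unifrac: length mismatch")
  if (sum(x) == 0 || sum(y) == 0) abort("unifrac: empty sample")
  ids <- names(x) %||% tree$tip.label[seq_along(x)]
  m <- rbind(x, y)
  colnames(m) <- ids
  # prune only to the taxon set of the input: taxa absent from BOTH samples
  # still shape the tree they share, and only branches with zero mass in both
  # samples may drop out
  bt <- branch_table(tree, ids)
  m <- m[, rownames(bt$M), drop = FALSE]
  unifrac_from_branches(m[1, ], m[2, ], bt, weighted)
}

unifrac_from_branches <- function(x, y, bt, weighted) {
  p <- (x / sum(x)) %*% bt$M
  q <- (y / sum(y)) %*% bt$M
  l <- bt$lengths
  if (weighted) {
    den <- sum(l * (p + q))
    if (den == 0) return(0)
    sum(l * abs(p - q)) / den
  } else {
    pp <- p > 0; qq <- q > 0
    den <- sum(l[pp | qq])
    if (den == 0) return(0)
    sum(l[xor(pp, qq)]) / den
  }
}

#' All pairwise community dissimilarities
#'
#' Builds the full symmetric matrix for one of the four supported measures:
#' `"bray_weighted"`, `"bray_unweighted"`, `"unifrac_weighted"`,
#' `"unifrac_unweighted"`.
#'
#' @param table a [count_table()] (rows may also be relative abundances for
#'   the Bray-Curtis measures, e.g. a functional profile).
#' @param measure one of the four measure tags.
#' @param tree rooted tree, required for the UniFrac measures.
#' @return a `comm_dist`: an n x n symmetric zero-diagonal matrix with a
#'   `measure` attribute.
#' @export
distance_matrix <- function(table,
                            measure = c("bray_weighted", "bray_unweighted",
                                        "unifrac_weighted", "unifrac_unweighted"),
                            tree = NULL) {
  measure <- match.arg(measure)
  m <- unclass(as.matrix(table))
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (startsWith(measure, "unifrac")) {
    if (is.null(tree)) abort("distance_matrix: UniFrac needs a tree")
    if (any(rowSums(m) == 0)) abort("distance_matrix: empty sample")
    bt <- branch_table(tree, colnames(m)[colSums(m) > 0])
    mm <- m[, rownames(bt$M), drop = FALSE]
    weighted <- measure == "unifrac_weighted"
    P <- (mm / rowSums(mm)) %*% bt$M          # n x edges branch mass
    l <- bt$lengths
    if (weighted) {
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        den <- sum(l * (P[i, ] + P[j, ]))
        D[i, j] <- D[j, i] <- if (den == 0) 0 else sum(l * abs(P[i, ] - P[j, ])) / den
      }
    } else {
      B <- P > 0
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        den <- sum(l[B[i, ] | B[j, ]])
        D[i, j] <- D[j, i] <- if (den == 0) 0 else sum(l[xor(B[i, ], B[j, ])]) / den
      }
    }
  } else {
    weighted <- measure == "bray_weighted"
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      D[i, j] <- D[j, i] <- bray_curtis(m[i, ], m[j, ], weighted = weighted)
  }
  structure(D, measure = measure, class = c("comm_dist", "matrix", "array"))
}

#' @export
print.comm_dist <- function(x, ...) {
  cat(sprintf("comm_dist (%s): %d samples, range [%.4g, %.4g]\n",
              attr(x, "measure"), nrow(x), min(x), max(x)))
  print(round(unclass(x), 4))
  invisible(x)
}
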