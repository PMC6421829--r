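#' Rarefy a count table to a fixed depth
#'
#' Each sample is subsampled WITHOUT replacement to exactly `depth` reads
#' (multivariate hypergeometric draw, the `rrarefy` semantics), so a sample
#' already at `depth` is returned unchanged. Columns (zOTUs) are preserved,
#' zeros included. Samples shallower than `depth` are an error: filter them
#' out first with [drop_low_depth()].
#'
#' @param table a [count_table()] or count matrix (samples in rows).
#' @param depth target reads per sample.
#' @param seed integer seed; the draw is fully reproducible and leaves the
#'   caller's RNG state untouched.
#' @return rarefied `count_table` with row sums all equal to `depth`.
#' @export
rarefy_counts <- function(table, depth, seed = NULL) {
  m <- unclass(as.matrix(table))
  d <- rowSums(m)
  low <- d < depth
  if (any(low))
    abort("rarefy_counts: sample(s) below depth %d: %s", depth,
          paste(sprintf("%s (%d)", rownames(m)[low], d[low]), collapse = ", "))
  out <- with_seed(seed, {
    t(apply(m, 1L, function(row) {
      N <- sum(row)
      if (N == depth) return(row)
      reads <- rep.int(seq_along(row), row)
      keep <- reads[sample.int(N, depth)]
      tabulate(keep, nbins = length(row))
    }))
  })
  dimnames(out) <- dimnames(m)
  count_table(out, fraction = attr(table, "fraction"))
}

#' Observed richness
#' @param x count vector, or matrix with samples in rows.
#' @return number of taxa with count > 0 (per sample).
#' @export
richness <- function(x) {
  if (is.matrix(x)) rowSums(unclass(x) > 0) else sum(x > 0)
}

#' Shannon diversity index (natural log)
#'
#' `H' = -sum(p_i * log(p_i))` over taxon proportions, nats; zero-count taxa
#' contribute nothing. Computed with [vegan::diversity()].
#'
#' @param x count vector, or matrix with samples in rows.
#' @return H' per sample.
#' @export
shannon_index <- function(x) {
  m <- if (is.matrix(x)) unclass(x) else matrix(x, nrow = 1)
  if (any(rowSums(m) == 0)) abort("shannon_index: all-zero sample")
  h <- vegan::diversity(m, index = "shannon")
  if (is.matrix(x)) h else unname(h)
}

#' Faith's phylogenetic diversity (root-inclusive)
#'
#' Total branch length of the minimal subtree connecting a community's taxa
#' and the root (the `include.root = TRUE` convention of `picante::pd`):
#' the sum of lengths of every branch with at least one present descendant.
#' The tree is first pruned to the full zOTU set of the input, so the root is
#' the basal node of that pruned tree. An empty community has PD 0.
#'
#' @param x count vector named by zOTU, or matrix with samples in rows and
#'   zOTU column names.
#' @param tree rooted [ape::phylo] tree whose tips cover every present taxon.
#' @return PD in branch-length units, per sample.
#' @export
faith_pd <- function(x, tree) {
  m <- if (is.matrix(x)) unclass(x) else {
    if (is.null(names(x))) abort("faith_pd: count vector must be named by zOTU")
    matrix(x, nrow = 1, dimnames = list("s", names(x)))
  }
  present <- colnames(m)[colSums(m) > 0]
  miss <- setdiff(present, tree$tip.label)
  if (length(miss))
    abort("faith_pd: taxa missing from tree: %s", paste(utils::head(miss, 5), collapse = ", "))
  keep <- intersect(colnames(m), tree$tip.label)
  bt <- branch_table(tree, keep)
  mm <- m[, rownames(bt$M), drop = FALSE]
  P <- (mm > 0) %*% bt$M            # samples x edges: present-descendant count
  pd <- as.numeric((P > 0) %*% bt$lengths)
  names(pd) <- rownames(m)
  if (is.matrix(x)) pd else unname(pd)
}

#' Analytic individual-based rarefaction curve
#'
#' Expected richness in a subsample of size `n` drawn without replacement:
#' `E[S_n] = sum_i (1 - choose(N - N_i, n)/choose(N, n))` (hypergeometric; no
#' resampling involved). Computed with [vegan::rarefy()].
#'
#' @param x count vector for one sample.
#' @param grid subsample sizes, each `<= sum(x)`.
#' @return a `rarefaction_curve` data.frame with columns `n`, `expected_richness`.
#' @export
rarefaction_curve <- function(x, grid) {
  N <- sum(x)
  if (any(grid > N)) abort("rarefaction_curve: grid point exceeds sample depth %d", N)
  if (any(grid < 1)) abort("rarefaction_curve: grid points must be >= 1")
  es <- as.numeric(suppressWarnings(vegan::rarefy(matrix(x, nrow = 1), sample = grid)))
  structure(data.frame(n = grid, expected_richness = es),
            class = c("rarefaction_curve", "data.frame"))
}

#' Sample-based species accumulation curve (exact method)
#'
#' Expected number of zOTUs seen in `k` samples drawn without replacement:
#' `E[S(k)] = sum_i (1 - choose(T - t_i, k)/choose(T, k))` with `T` samples in
#' total and `t_i` the number containing taxon `i`. Computed with
#' [vegan::specaccum()], method `"exact"`.
#'
#' @param table a [count_table()].
#' @param k_grid sample counts, each `<= nrow(table)` (default all of `1:T`).
#' @return data.frame with columns `k`, `expected_richness`.
#' @export
species_accumulation <- function(table, k_grid = seq_len(nrow(table))) {
  T_ <- nrow(table)
  if (any(k_grid > T_)) abort("species_accumulation: k exceeds number of samples %d", T_)
  sa <- suppressWarnings(vegan::specaccum(unclass(as.matrix(table)), method = "exact"))
  data.frame(k = k_grid, expected_richness = sa$richness[k_grid])
}

#' Fit the Michaelis-Menten (MM2) saturation model to a curve
#'
#' Least-squares fit of `y = d * x / (e + x)`; the asymptote `d` estimates
#' total richness and `e` is the half-saturation effort. Started from
#' `d0 = max(y)` and `e0 = x` at the point closest to `d0/2`, refined with
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]) to a relative tolerance of
#' 1e-8. A constant-y curve is degenerate and reported as not converged.
#'
#' @param x positive effort values (reads or samples).
#' @param y response (expected richness), same length.
#' @return an `mm_fit` with fields `d`, `e`, `rss`, `converged`, `message`;
#'   methods: `print`, `coef`, `predict`, `fitted`, `residuals`.
#' @examples
#' f <- fit_michaelis_menten(c(10, 50, 100, 500), 100 * c(10, 50, 100, 500) /
#'   (50 + c(10, 50, 100, 500)))
#' coef(f)
#' @export
fit_michaelis_menten <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    abort("fit_michaelis_menten: need >= 3 (x, y) pairs")
  if (any(x <= 0)) abort("fit_michaelis_menten: x must be positive")
  out <- list(d = NA_real_, e = NA_real_, rss = NA_real_, converged = FALSE,
              message = "", x = x, y = y)
  class(out) <- "mm_fit"
  if (stats::sd(y) == 0) {
    out$message <- "constant response; asymptote not identifiable"
    return(out)
  }
  d0 <- max(y)
  e0 <- max(x[which.min(abs(y - d0 / 2))], min(x) / 2)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ d * x / (e + x),
                      start = list(d = d0, e = e0),
                      lower = c(d = .Machine$double.eps, e = .Machine$double.eps),
                      control = minpack.lm::nls.lm.control(
                        ftol = 1e-10, ptol = 1e-10, maxiter = 500)),
    error = function(err) err)
  if (inherits(fit, "error")) {
    out$message <- conditionMessage(fit)
    return(out)
  }
  cf <- stats::coef(fit)
  out$d <- unname(cf["d"]); out$e <- unname(cf["e"])
  out$rss <- sum(stats::resid(fit)^2)
  out$converged <- is.finite(out$d) && is.finite(out$e) && out$d > 0 && out$e > 0
  out
}

#' @export
print.mm_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("Michaelis-Menten fit: d (asymptote) = %.4f, e (half-saturation) = %.4f, RSS = %.4g\n",
                x$d, x$e, x$rss))
  else cat("Michaelis-Menten fit: NOT converged -", x$message, "\n")
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) c(d = object$d, e = object$e)

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else
    if (is.list(newdata)) newdata$x else newdata
  object$d * x / (object$e + x)
}

#' @export
fitted.mm_fit <- function(object, ...) predict(object)

#' @export
residuals.mm_fit <- function(object, ...) object$y - fitted(object)

#' Coverage from an MM asymptote
#'
#' `100 * S_obs / d`: the fraction of the estimated total richness recovered
#' by the surveying effort. Values above 100 (observed richness exceeding the
#' fitted asymptote) are returned as-is with a warning, never clamped.
#'
#' @param s_obs observed richness.
#' @param fit a converged [fit_michaelis_menten()] result.
#' @return coverage percentage, with attribute `exceeds_asymptote` when > 100.
#' @export
coverage_estimate <- function(s_obs, fit) {
  if (!inherits(fit, "mm_fit")) abort("coverage_estimate: need an mm_fit")
  if (!fit$converged) abort("coverage_estimate: MM fit did not converge")
  cov <- 100 * s_obs / fit$d
  if (cov > 100) {
    warning("observed richness exceeds fitted asymptote (coverage > 100%)",
            call. = FALSE)
    attr(cov, "exceeds_asymptote") <- TRUE
  }
  cov
}

#' Repeated-rarefaction alpha-diversity profile
#'
#' The study protocol: rarefy the table `iterations` times (default 100), in
#' each round compute richness, Shannon H' and Faith's PD per sample, and
#' report the arithmetic mean over rounds. Per-sample coverage comes from a
#' Michaelis-Menten fit to the rarefaction curve: by default the analytic
#' curve of each rarefied table, averaged over rounds (`"mean_curve"`);
#' alternatively one MM fit per round with coverages averaged afterwards
#' (`"per_iteration"`).
#'
#' @param table a [count_table()]; all samples must have depth >= `depth`.
#' @param tree rooted tree for Faith's PD.
#' @param depth rarefaction depth.
#' @param iterations rarefaction rounds (study default 100).
#' @param seed global seed; round `i` uses `derive_seed(seed, i)`.
#' @param coverage_method `"mean_curve"` (default) or `"per_iteration"`.
#' @param curve_points number of grid points for the rarefaction curve.
#' @return an `alpha_profile` data.frame: one row per sample with columns
#'   `richness`, `shannon`, `faith_pd`, `coverage`, `mm_d`, `mm_e`,
#'   `mm_converged` (plus `fraction` when the table is tagged).
#' @export
alpha_profile <- function(table, tree, depth, iterations = 100, seed = 1,
                          coverage_method = c("mean_curve", "per_iteration"),
                          curve_points = 25) {
  coverage_method <- match.arg(coverage_method)
  n <- nrow(table)
  grid <- unique(round(seq(1, depth, length.out = curve_points)))
  S <- H <- PD <- matrix(NA_real_, iterations, n)
  curves <- matrix(0, n, length(grid))
  covs <- matrix(NA_real_, iterations, n)
  for (i in seq_len(iterations)) {
    rt <- rarefy_counts(table, depth, seed = derive_seed(seed, i))
    m <- unclass(rt)
    S[i, ] <- richness(m)
    H[i, ] <- shannon_index(m)
    PD[i, ] <- faith_pd(m, tree)
    cur <- t(vapply(seq_len(n), function(s)
      rarefaction_curve(m[s, ], grid)$expected_richness, numeric(length(grid))))
    if (coverage_method == "mean_curve") {
      curves <- curves + cur
    } else {
      for (s in seq_len(n)) {
        f <- fit_michaelis_menten(grid, cur[s, ])
        covs[i, s] <- if (f$converged) 100 * S[i, s] / f$d else NA_real_
      }
    }
  }
  s_mean <- colMeans(S)
  res <- data.frame(sample_id = rownames(table),
                    richness = s_mean, shannon = colMeans(H),
                    faith_pd = colMeans(PD),
                    coverage = NA_real_, mm_d = NA_real_, mm_e = NA_real_,
                    mm_converged = FALSE, stringsAsFactors = FALSE)
  if (coverage_method == "mean_curve") {
    curves <- curves / iterations
    for (s in seq_len(n)) {
      f <- fit_michaelis_menten(grid, curves[s, ])
      res$mm_converged[s] <- f$converged
      if (f$converged) {
        res$mm_d[s] <- f$d; res$mm_e[s] <- f$e
        res$coverage[s] <- 100 * s_mean[s] / f$d
      }
    }
    attr(res, "mean_curves") <- curves
  } else {
    res$coverage <- colMeans(covs, na.rm = TRUE)
    res$mm_converged <- colSums(!is.na(covs)) > 0
  }
  fr <- attr(table, "fraction")
  if (!is.null(fr)) res$fraction <- unname(fr[res$sample_id])
  attr(res, "depth") <- depth
  attr(res, "iterations") <- iterations
  attr(res, "seed") <- seed
  attr(res, "curve_grid") <- grid
  class(res) <- c("alpha_profile", "data.frame")
  res
}

#' @export
print.alpha_profile <- function(x, ...) {
  cat(sprintf("alpha_profile: %d samples, depth %d, %d rarefaction iteration(s)\n",
              nrow(x), attr(x, "depth"), attr(x, "iterations")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(col) round(col, 3))
  print(df, row.names = FALSE)
  invisible(x)
}
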