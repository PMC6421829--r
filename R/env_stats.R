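#' Spearman rank correlation test
#'
#' Wrapper around [stats::cor.test()] with the study conventions: pairwise
#' deletion of missing values first; exact two-sided p by the permutation
#' null distribution of the rank statistic when `n <= 9` and the data are
#' tie-free, otherwise the t-approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` df (midranks for ties).
#'
#' @param x,y paired numeric vectors.
#' @param alpha significance threshold for the `significant` flag.
#' @return list with `rho`, `p`, `n`, `method` (`"exact"`/`"t-approx"`),
#'   `significant`.
#' @export
spearman_test <- function(x, y, alpha = 0.05) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("spearman_test: need >= 3 complete pairs (have %d)", n)
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0)
    abort("spearman_test: zero variance in ranks")
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  exact <- n <= 9 && !ties
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact,
                    alternative = "two.sided"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n,
       method = if (exact) "exact" else "t-approx",
       significant = ct$p.value <= alpha)
}

#' Pairwise Spearman correlation matrix of environmental properties
#'
#' All property pairs, pairwise-complete; the diagonal is rho = 1 with p NA
#' by convention.
#'
#' @param env an [env_table()] (or numeric data.frame).
#' @param alpha significance threshold.
#' @return an `env_corr` list with symmetric matrices `rho`, `p`, `n` and a
#'   long-format `table` (one row per unordered pair).
#' @export
correlation_matrix <- function(env, alpha = 0.05) {
  df <- as.data.frame(env)
  props <- names(df)
  k <- length(props)
  if (k < 2) abort("correlation_matrix: need >= 2 properties")
  rho <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(props, props))
  diag(rho) <- 1
  rows <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    res <- tryCatch(spearman_test(df[[i]], df[[j]], alpha = alpha),
                    error = function(e) NULL)
    if (!is.null(res)) {
      rho[i, j] <- rho[j, i] <- res$rho
      p[i, j] <- p[j, i] <- res$p
      nmat[i, j] <- nmat[j, i] <- res$n
      rows[[length(rows) + 1L]] <- data.frame(
        property_1 = props[i], property_2 = props[j], rho = res$rho,
        p = res$p, n = res$n, significant = res$significant,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(rho = rho, p = p, n = nmat,
                 table = do.call(rbind, rows), alpha = alpha),
            class = "env_corr")
}

#' @export
print.env_corr <- function(x, ...) {
  cat("Spearman correlations between environmental properties\n")
  print(round(x$rho, 2))
  nsig <- sum(x$table$significant, na.rm = TRUE)
  cat(sprintf("%d of %d pairs significant at p <= %g\n",
              nsig, nrow(x$table), x$alpha))
  invisible(x)
}

#' Remove low-depth libraries before statistical analysis
#'
#' Libraries with fewer reads than `min_depth` cannot be rarefied to that
#' depth and are removed up front (the study removed four RNA libraries this
#' way). The removal report travels as an attribute and is printed as a
#' message.
#'
#' @param table a [count_table()].
#' @param min_depth minimum library size kept (typically the rarefaction depth).
#' @param quiet suppress the removal message.
#' @return filtered `count_table` with attribute `removed` (data.frame of
#'   dropped sample ids and depths).
#' @export
drop_low_depth <- function(table, min_depth, quiet = FALSE) {
  if (min_depth < 0) abort("drop_low_depth: min_depth must be >= 0")
  d <- sample_depths(table)
  drop <- d < min_depth
  report <- data.frame(sample_id = rownames(table)[drop], depth = unname(d[drop]),
                       row.names = NULL, stringsAsFactors = FALSE)
  if (all(drop)) abort("drop_low_depth: no sample reaches depth %d", min_depth)
  out <- table[!drop, ]
  if (!quiet && nrow(report))
    message(sprintf("drop_low_depth: removed %d sample(s) below %d reads: %s",
                    nrow(report), min_depth,
                    paste(sprintf("%s (%d)", report$sample_id, report$depth),
                          collapse = ", ")))
  attr(out, "removed") <- report
  out
}

#' Integrate a chlorophyll depth profile
#'
#' The primary-productivity proxy: the sum of chlorophyll concentrations
#' measured in the top `max_depth` metres of the water column (default 500 m).
#'
#' @param profile data.frame with columns `depth` (m) and `concentration`.
#' @param max_depth integration cutoff in metres.
#' @return summed concentration over readings at depths `<= max_depth`.
#' @export
integrate_chlorophyll <- function(profile, max_depth = 500) {
  if (!all(c("depth", "concentration") %in% names(profile)))
    abort("integrate_chlorophyll: profile needs 'depth' and 'concentration' columns")
  if (nrow(profile) == 0) abort("integrate_chlorophyll: empty profile")
  if (any(profile$depth < 0)) abort("integrate_chlorophyll: negative depth")
  sum(profile$concentration[profile$depth <= max_depth])
}

#' Screen alpha-diversity indices against environmental properties
#'
#' One Spearman test per (index, property) combination, DNA and RNA fractions
#' always screened separately. Degenerate combinations (constant index or
#' property) yield an NA row with a diagnostic note rather than an error.
#'
#' @param alpha an [alpha_profile()] (needs a `fraction` column when both
#'   fractions are present).
#' @param env an [env_table()] with rownames matching the profile's samples.
#' @param indices profile columns to screen.
#' @param alpha_level significance threshold.
#' @return a `screen_table` data.frame: one row per
#'   (index, property, fraction) with `rho`, `p`, `significant`, `note`.
#' @export
alpha_env_screen <- function(alpha, env,
                             indices = c("richness", "shannon", "faith_pd", "coverage"),
                             alpha_level = 0.05) {
  df <- as.data.frame(alpha)
  fracs <- if ("fraction" %in% names(df)) unique(df$fraction) else NA_character_
  props <- names(as.data.frame(env))
  rows <- list()
  for (fr in fracs) {
    sub <- if (is.na(fr)) df else df[df$fraction == fr, , drop = FALSE]
    e <- as.data.frame(env)[sub$sample_id, , drop = FALSE]
    for (idx in indices) for (pr in props) {
      res <- tryCatch(spearman_test(sub[[idx]], e[[pr]], alpha = alpha_level),
                      error = function(err) conditionMessage(err))
      rows[[length(rows) + 1L]] <- if (is.character(res))
        data.frame(response = idx, property = pr, fraction = fr,
                   statistic = NA_real_, p = NA_real_, significant = NA,
                   note = res, stringsAsFactors = FALSE)
      else
        data.frame(response = idx, property = pr, fraction = fr,
                   statistic = res$rho, p = res$p, significant = res$significant,
                   note = "", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "statistic") <- "spearman_rho"
  attr(out, "alpha") <- alpha_level
  class(out) <- c("screen_table", "data.frame")
  out
}

#' Repeated-rarefaction PERMANOVA screen of composition vs environment
#'
#' One [permanova_rarefied()]-style test per (property, measure, fraction)
#' triple, DNA and RNA arms never pooled. To avoid redundant work the `R`
#' rarefactions (and their four distance matrices) are shared across the
#' properties and measures of one fraction; permutation draws are fresh per
#' (rarefaction, property). Samples with NA in a property are dropped for
#' that property only.
#'
#' @param table a [count_table()] with fraction tags (already depth-filtered).
#' @param env an [env_table()] covering the table's samples.
#' @param tree rooted tree (needed for the UniFrac measures).
#' @param depths named list/vector of rarefaction depths per fraction,
#'   e.g. `c(DNA = 9058, RNA = 4941)`.
#' @param rarefactions rounds `R` per test (study protocol 999).
#' @param n_perm permutations `K` per rarefaction.
#' @param seed global seed.
#' @param measures distance measures to screen (default all four).
#' @param properties env columns to screen (default all numeric columns).
#' @param alpha_level significance threshold.
#' @return a `screen_table`: rows of (property, measure, fraction) with mean
#'   pseudo-F (`statistic`), mean `R2` and pooled `p`.
#' @export
beta_env_screen <- function(table, env, tree = NULL,
                            depths = c(DNA = 9058, RNA = 4941),
                            rarefactions = 999, n_perm = 999, seed = 1,
                            measures = c("bray_weighted", "bray_unweighted",
                                         "unifrac_weighted", "unifrac_unweighted"),
                            properties = NULL, alpha_level = 0.05) {
  fr_tags <- attr(table, "fraction")
  fracs <- if (is.null(fr_tags)) stats::setNames(NA_character_, "all") else
    intersect(c("DNA", "RNA"), unique(fr_tags))
  edf <- as.data.frame(env)
  properties <- properties %||% names(edf)[vapply(edf, is.numeric, logical(1))]
  if (any(startsWith(measures, "unifrac")) && is.null(tree))
    abort("beta_env_screen: UniFrac measures need a tree")
  rows <- list()
  for (fi in seq_along(fracs)) {
    fr <- fracs[fi]
    sub <- if (is.na(fr)) table else subset_fraction(table, fr)
    depth <- if (is.na(fr)) depths[[1L]] else depths[[fr]]
    e <- edf[rownames(sub), , drop = FALSE]
    fseed <- derive_seed(seed, 100000L + fi)
    acc <- screen_permanova_pool(sub, e, properties, measures, tree,
                                 depth, rarefactions, n_perm, fseed)
    acc$fraction <- fr
    rows[[length(rows) + 1L]] <- acc
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p <= alpha_level
  out <- out[, c("response", "property", "fraction", "measure",
                 "statistic", "R2", "p", "significant")]
  attr(out, "statistic") <- "pseudo_F"
  attr(out, "alpha") <- alpha_level
  attr(out, "rarefactions") <- rarefactions
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("screen_table", "data.frame")
  out
}

# shared-rarefaction engine behind beta_env_screen: one rarefied table feeds
# every measure x property cell of a fraction.
screen_permanova_pool <- function(table, e, properties, measures, tree,
                                  depth, R, K, seed) {
  n <- nrow(table)
  cells <- expand.grid(property = properties, measure = measures,
                       stringsAsFactors = FALSE)
  Fsum <- R2sum <- exceed <- numeric(nrow(cells))
  nused <- integer(nrow(cells))
  for (r in seq_len(R)) {
    rt <- rarefy_counts(table, depth, seed = derive_seed(seed, r))
    Ds <- lapply(measures, function(msr) distance_matrix(rt, msr, tree = tree))
    names(Ds) <- measures
    Gs <- lapply(Ds, gower_center)
    for (ci in seq_len(nrow(cells))) {
      pr <- cells$property[ci]; msr <- cells$measure[ci]
      x <- e[[pr]]
      ok <- !is.na(x)
      G <- Gs[[msr]]
      if (!all(ok)) G <- gower_center(unclass(Ds[[msr]])[ok, ok])
      obs <- pseudo_f(G, x[ok])
      eps <- sqrt(.Machine$double.eps) * max(1, abs(obs$F))
      Fsum[ci] <- Fsum[ci] + obs$F
      R2sum[ci] <- R2sum[ci] + obs$R2
      if (K > 0) {
        perms <- with_seed(derive_seed(seed, R + (r - 1L) * nrow(cells) + ci),
                           t(replicate(K, sample.int(sum(ok)))))
        Fk <- perm_f_values(G, obs$H, perms, obs$df_model, obs$df_resid)
        exceed[ci] <- exceed[ci] + sum(Fk >= obs$F - eps)
      }
      nused[ci] <- sum(ok)
    }
  }
  data.frame(response = "composition", property = cells$property,
             measure = cells$measure, statistic = Fsum / R, R2 = R2sum / R,
             p = if (K > 0) (1 + exceed) / (1 + R * K) else NA_real_,
             n = nused, stringsAsFactors = FALSE)
}

#' PERMANOVA screen of functional profiles vs environment
#'
#' Functional profiles are relative abundances, so no rarefaction is applied:
#' a weighted Bray-Curtis matrix is built once per fraction and tested with
#' [permanova_single()] per property.
#'
#' @param functions sample x function relative-abundance matrix (or
#'   `count_table`-like object); rownames are sample ids.
#' @param env an [env_table()] covering the samples.
#' @param fraction optional named fraction tags for the samples.
#' @param n_perm permutations per test.
#' @param seed global seed.
#' @param properties env columns to screen.
#' @param alpha_level significance threshold.
#' @return a `screen_table` with one row per (property, fraction).
#' @export
function_screen <- function(functions, env, fraction = NULL, n_perm = 999,
                            seed = 1, properties = NULL, alpha_level = 0.05) {
  m <- as.matrix(functions)
  if (any(m < 0)) abort("function_screen: negative abundances")
  fraction <- fraction %||% attr(functions, "fraction")
  fracs <- if (is.null(fraction)) NA_character_ else
    intersect(c("DNA", "RNA"), unique(fraction))
  edf <- as.data.frame(env)
  properties <- properties %||% names(edf)[vapply(edf, is.numeric, logical(1))]
  rows <- list()
  for (fi in seq_along(fracs)) {
    fr <- fracs[fi]
    sub <- if (is.na(fr)) m else m[names(fraction)[fraction == fr], , drop = FALSE]
    D <- distance_matrix(sub, "bray_weighted")
    e <- edf[rownames(sub), , drop = FALSE]
    for (pi in seq_along(properties)) {
      pr <- properties[pi]
      x <- e[[pr]]; ok <- !is.na(x)
      Dsub <- structure(unclass(D)[ok, ok], measure = "bray_weighted")
      res <- tryCatch(
        permanova_single(Dsub, x[ok], n_perm = n_perm,
                         seed = derive_seed(seed, fi * 1000L + pi)),
        error = function(err) conditionMessage(err))
      rows[[length(rows) + 1L]] <- if (is.character(res))
        data.frame(response = "function", property = pr, fraction = fr,
                   measure = "bray_weighted", statistic = NA_real_,
                   R2 = NA_real_, p = NA_real_, significant = NA,
                   stringsAsFactors = FALSE)
      else
        data.frame(response = "function", property = pr, fraction = fr,
                   measure = "bray_weighted", statistic = res$F, R2 = res$R2,
                   p = res$p, significant = res$p <= alpha_level,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "statistic") <- "pseudo_F"
  attr(out, "alpha") <- alpha_level
  class(out) <- c("screen_table", "data.frame")
  out
}

#' @export
print.screen_table <- function(x, ...) {
  cat(sprintf("screen_table: %d tests (%s), %d significant at p <= %g\n",
              nrow(x), attr(x, "statistic") %||% "statistic",
              sum(x$significant, na.rm = TRUE), attr(x, "alpha") %||% 0.05))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(col) signif(col, 4))
  print(df, row.names = FALSE)
  invisible(x)
}
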