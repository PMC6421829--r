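#' Gower-centre a dissimilarity matrix
#'
#' Forms `A = -D^2/2` elementwise and double-centres it,
#' `G = (I - 11'/n) A (I - 11'/n)`. By the Huygens identity
#' `tr(G) = (1/n) * sum_{i<j} D_ij^2` is the total sum of squares of the
#' distance-based ANOVA (McArdle-Anderson formulation used by `adonis`).
#'
#' @param D symmetric dissimilarity matrix (a `comm_dist` or plain matrix).
#' @return centred matrix `G` with attribute `ss_total`.
#' @export
gower_center <- function(D) {
  D <- unclass(as.matrix(D))
  if (nrow(D) != ncol(D)) abort("gower_center: matrix not square")
  A <- -0.5 * D * D
  n <- nrow(D)
  rm_ <- rowMeans(A); gm <- mean(A)
  G <- A - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm
  attr(G, "ss_total") <- sum(diag(G))
  G
}

#' Pseudo-F statistic for one covariate on a centred distance matrix
#'
#' With hat matrix `H` of the design `[1, x]`:
#' `SS_model = tr(HGH)`, `SS_resid = tr((I-H)G(I-H))`,
#' `F = (SS_model/df_m) / (SS_resid/df_r)`, `R2 = SS_model / tr(G)`.
#' Because `G` is double-centred these traces reduce to `sum(G * H)` and
#' `tr(G) - sum(G * H)`.
#'
#' @param G Gower-centred matrix from [gower_center()].
#' @param x numeric covariate or factor, length `n`, no `NA`.
#' @return list with `F`, `R2`, `df_model`, `df_resid`, `ss_model`,
#'   `ss_resid`, `ss_total`.
#' @export
pseudo_f <- function(G, x) {
  n <- nrow(G)
  if (length(x) != n) abort("pseudo_f: covariate length != n")
  if (anyNA(x)) abort("pseudo_f: NA in covariate; drop those samples first")
  X <- stats::model.matrix(~x, data = data.frame(x = x))
  qr_ <- qr(X)
  if (qr_$rank < 2L) abort("pseudo_f: covariate is constant (rank-deficient design)")
  H <- tcrossprod(qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE])
  ss_total <- attr(G, "ss_total") %||% sum(diag(G))
  ss_model <- sum(G * H)
  ss_resid <- ss_total - ss_model
  df_m <- qr_$rank - 1L
  df_r <- n - qr_$rank
  list(F = (ss_model / df_m) / (ss_resid / df_r),
       R2 = if (ss_total > 0) ss_model / ss_total else NA_real_,
       df_model = df_m, df_resid = df_r,
       ss_model = ss_model, ss_resid = ss_resid, ss_total = ss_total,
       H = H)
}

# permuted pseudo-F values for a fixed H: permuting the covariate equals
# permuting H's rows and columns, so each permutation costs one n x n
# elementwise product.
perm_f_values <- function(G, H, perms, df_m, df_r) {
  ss_total <- attr(G, "ss_total") %||% sum(diag(G))
  apply(perms, 1L, function(p) {
    ssm <- sum(G * H[p, p])
    (ssm / df_m) / ((ss_total - ssm) / df_r)
  })
}

#' Single-covariate PERMANOVA on a fixed distance matrix
#'
#' Permutation test of the [pseudo_f()] statistic under free relabelling of
#' the covariate. The p-value uses the epsilon correction: permuted statistics
#' within `eps = sqrt(.Machine$double.eps) * max(1, |F_obs|)` of the observed
#' value count as exceedances, so floating-point ties can never make the test
#' anti-conservative. With `K` random permutations
#' `p = (1 + #\{F_k >= F_obs - eps\}) / (1 + K)`, hence `p >= 1/(1+K) > 0`.
#'
#' @param D dissimilarity matrix.
#' @param x covariate (numeric or factor), aligned to `D`'s rows.
#' @param n_perm number of random permutations `K` (0 gives `p = NA`).
#' @param seed integer seed for the permutation draw.
#' @param permutations optional explicit permutation matrix (one permutation
#'   per row, e.g. all `n!` relabelings); when supplied, `p` is the exact
#'   fraction of listed permutations with `F* >= F_obs - eps` and `n_perm`
#'   is ignored.
#' @return a `permanova` object.
#' @export
permanova_single <- function(D, x, n_perm = 999, seed = NULL, permutations = NULL) {
  G <- gower_center(D)
  obs <- pseudo_f(G, x)
  eps <- sqrt(.Machine$double.eps) * max(1, abs(obs$F))
  if (!is.null(permutations)) {
    Fk <- perm_f_values(G, obs$H, permutations, obs$df_model, obs$df_resid)
    p <- mean(Fk >= obs$F - eps)
    K <- nrow(permutations)
  } else if (n_perm > 0) {
    n <- nrow(G)
    perms <- with_seed(seed, t(replicate(n_perm, sample.int(n))))
    Fk <- perm_f_values(G, obs$H, perms, obs$df_model, obs$df_resid)
    p <- (1 + sum(Fk >= obs$F - eps)) / (1 + n_perm)
    K <- n_perm
  } else {
    Fk <- numeric(0); p <- NA_real_; K <- 0L
  }
  structure(list(covariate = deparse1(substitute(x)), F = obs$F, R2 = obs$R2,
                 p = p, df_model = obs$df_model, df_resid = obs$df_resid,
                 n_perm = K, n_rarefactions = 1L, epsilon = eps,
                 measure = attr(D, "measure") %||% NA_character_,
                 seed = seed, perm_F = Fk),
            class = "permanova")
}

#' Repeated-rarefaction PERMANOVA
#'
#' The distance matrix of a rarefied count table depends on the random
#' subsample, so the table is rarefied `R` times; each rarefaction `r` yields
#' its own observed statistic `F_r` and `K` permuted statistics, and the
#' per-rarefaction exceedance counts (epsilon-corrected, as in
#' [permanova_single()]) are pooled into one overall p-value
#' `p = (1 + sum_r #\{F_{r,k} >= F_r - eps_r\}) / (1 + R K)`. Reported `F` and
#' `R2` are means over rarefactions; the full per-rarefaction trace is kept.
#'
#' With `R = 1` the result is identical to [permanova_single()] run on
#' `rarefy_counts(table, depth, derive_seed(seed, 1))` with permutation seed
#' `derive_seed(seed, 1 + R)`.
#'
#' @param table a [count_table()]; every sample must have depth >= `depth`.
#' @param x covariate aligned to the table's samples.
#' @param measure one of the four [distance_matrix()] measures.
#' @param tree required for UniFrac measures.
#' @param depth rarefaction depth (reads per sample).
#' @param rarefactions number of rarefaction rounds `R` (study protocol: 999).
#' @param n_perm permutations per rarefaction `K`.
#' @param seed global seed; all child seeds derive from it.
#' @param reuse_permutations draw one permutation set and reuse it across all
#'   rarefactions instead of drawing fresh permutations each round.
#' @return a `permanova` object (class also `rr_permanova`) with a
#'   `trace` data.frame of per-rarefaction `F`, `R2` and exceedance counts.
#' @export
permanova_rarefied <- function(table, x, measure = "bray_weighted", tree = NULL,
                               depth, rarefactions = 999, n_perm = 999,
                               seed = 1, reuse_permutations = FALSE) {
  if (anyNA(x)) abort("permanova_rarefied: NA in covariate; drop those samples first")
  n <- nrow(table)
  R <- rarefactions
  shared_perms <- if (reuse_permutations && n_perm > 0)
    with_seed(derive_seed(seed, 0L), t(replicate(n_perm, sample.int(n))))
  Fr <- R2r <- epsr <- numeric(R); exceed <- integer(R)
  for (r in seq_len(R)) {
    rt <- rarefy_counts(table, depth, seed = derive_seed(seed, r))
    D <- distance_matrix(rt, measure = measure, tree = tree)
    G <- gower_center(D)
    obs <- pseudo_f(G, x)
    eps <- sqrt(.Machine$double.eps) * max(1, abs(obs$F))
    Fr[r] <- obs$F; R2r[r] <- obs$R2; epsr[r] <- eps
    if (n_perm > 0) {
      perms <- if (reuse_permutations) shared_perms else
        with_seed(derive_seed(seed, R + r), t(replicate(n_perm, sample.int(n))))
      Fk <- perm_f_values(G, obs$H, perms, obs$df_model, obs$df_resid)
      exceed[r] <- sum(Fk >= obs$F - eps)
    }
  }
  p <- if (n_perm > 0) (1 + sum(exceed)) / (1 + R * n_perm) else NA_real_
  structure(list(covariate = deparse1(substitute(x)), F = mean(Fr), R2 = mean(R2r),
                 p = p, df_model = 1L, df_resid = n - 2L,
                 n_perm = n_perm, n_rarefactions = R,
                 epsilon = mean(epsr), measure = measure, depth = depth,
                 seed = seed,
                 trace = data.frame(rarefaction = seq_len(R), F = Fr, R2 = R2r,
                                    exceedances = exceed)),
            class = c("rr_permanova", "permanova"))
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (pseudo-F permutation test)\n")
  if (!is.na(x$measure %||% NA)) cat("  measure:      ", x$measure, "\n")
  cat(sprintf("  pseudo-F:      %.4f  (df %d, %d)\n", x$F, x$df_model, x$df_resid))
  cat(sprintf("  R2:            %.4f\n", x$R2))
  cat(sprintf("  p:             %.4g  (%d rarefaction(s) x %d permutation(s), epsilon %.3g)\n",
              x$p, x$n_rarefactions, x$n_perm, x$epsilon))
  invisible(x)
}

#' @export
summary.permanova <- function(object, ...) {
  out <- object[c("covariate", "F", "R2", "p", "df_model", "df_resid",
                  "n_perm", "n_rarefactions", "epsilon", "measure")]
  if (!is.null(object$trace)) {
    out$F_range <- range(object$trace$F)
    out$R2_range <- range(object$trace$R2)
  }
  class(out) <- "summary.permanova"
  out
}

#' @export
print.summary.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: F = %.4f, R2 = %.4f, p = %.4g (df %d/%d)\n",
              x$F, x$R2, x$p, x$df_model, x$df_resid))
  if (!is.null(x$F_range))
    cat(sprintf("  per-rarefaction F in [%.3f, %.3f], R2 in [%.3f, %.3f]\n",
                x$F_range[1], x$F_range[2], x$R2_range[1], x$R2_range[2]))
  invisible(x)
}
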