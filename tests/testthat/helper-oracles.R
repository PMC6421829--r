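# Independent oracles and small fixture builders shared across the suite.
# Everything here is deliberately brute-force / closed-form and never calls
# the package code paths it is used to check.

toy_tree <- function(text = "((A:1,B:2):3,C:4);") ape::read.tree(text = text)

toy_counts <- function(m = rbind(s1 = c(a = 1, b = 2, c = 3),
                                 s2 = c(a = 4, b = 0, c = 0)), ...) {
  count_table(m, ...)
}

# all n! permutations of 1:n (recursive; fine for n <= 7)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# classical multivariate sums-of-squares pseudo-F on raw coordinates:
# project each column of Y on the design [1, x] and pool SS across columns
ssq_pseudo_f <- function(Y, x) {
  Y <- as.matrix(Y)
  X <- stats::model.matrix(~x, data.frame(x = x))
  H <- X %*% solve(crossprod(X)) %*% t(X)
  n <- nrow(Y)
  C <- diag(n) - matrix(1 / n, n, n)
  Yc <- C %*% Y
  fit <- H %*% Yc
  ss_model <- sum(fit^2)
  ss_resid <- sum((Yc - fit)^2)
  df_m <- qr(X)$rank - 1L
  df_r <- n - qr(X)$rank
  list(F = (ss_model / df_m) / (ss_resid / df_r),
       R2 = ss_model / sum(Yc^2))
}

# grid-search least-squares oracle for y = d*x/(e+x): e scanned at `res`
# resolution, d solved in closed form per e (the model is linear in d)
mm_grid_oracle <- function(x, y, e_range = c(1, 200), res = 0.1) {
  es <- seq(e_range[1], e_range[2], by = res)
  best <- c(d = NA, e = NA, rss = Inf)
  for (e in es) {
    g <- x / (e + x)
    d <- sum(y * g) / sum(g * g)
    rss <- sum((y - d * g)^2)
    if (rss < best["rss"]) best <- c(d = d, e = e, rss = rss)
  }
  best
}

# exact two-sided Spearman permutation p by full enumeration
spearman_enum_p <- function(x, y) {
  n <- length(x)
  perms <- all_perms(n)
  rho_obs <- stats::cor(x, y, method = "spearman")
  rhos <- apply(perms, 1, function(p) stats::cor(x, y[p], method = "spearman"))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# exact PERMANOVA p by full enumeration of covariate relabelings
permanova_enum_p <- function(D, x) {
  n <- nrow(D)
  G <- gower_center(D)
  f_of <- function(xx) pseudo_f(G, xx)$F
  f_obs <- f_of(x)
  perms <- all_perms(n)
  fs <- apply(perms, 1, function(p) f_of(x[p]))
  mean(fs >= f_obs - sqrt(.Machine$double.eps) * max(1, abs(f_obs)))
}

expect_symmetric_zero_diag <- function(D) {
  expect_equal(unclass(D), t(unclass(D)))
  expect_equal(unname(diag(D)), rep(0, nrow(D)))
  expect_true(all(D >= 0) && all(D <= 1 + 1e-12))
}
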